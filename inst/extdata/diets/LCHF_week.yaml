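scheme: LCHF
meals:
- start_h: 8.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 13.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 19.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 32.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 37.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 43.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 56.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 61.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 67.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 80.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 85.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 91.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 104.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 109.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 115.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 128.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 133.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 139.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 152.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 157.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
- start_h: 163.0
  duration_min: 15.0
  carb_g: 50.0
  protein_g: 41.6666667
  fat_g: 33.3333333
  kcal: 666.6666667
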