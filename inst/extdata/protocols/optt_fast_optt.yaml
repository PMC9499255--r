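scheme: custom
meals:
- start_h: 8.0
  duration_min: 15.0
  carb_g: 75.7575758
  protein_g: 45.4545455
  fat_g: 20.2020202
  kcal: 666.6666667
- start_h: 13.0
  duration_min: 15.0
  carb_g: 75.7575758
  protein_g: 45.4545455
  fat_g: 20.2020202
  kcal: 666.6666667
- start_h: 19.0
  duration_min: 15.0
  carb_g: 75.7575758
  protein_g: 45.4545455
  fat_g: 20.2020202
  kcal: 666.6666667
- start_h: 32.0
  duration_min: 15.0
  carb_g: 75.7575758
  protein_g: 45.4545455
  fat_g: 20.2020202
  kcal: 666.6666667
- start_h: 37.0
  duration_min: 15.0
  carb_g: 75.7575758
  protein_g: 45.4545455
  fat_g: 20.2020202
  kcal: 666.6666667
- start_h: 43.0
  duration_min: 15.0
  carb_g: 75.7575758
  protein_g: 45.4545455
  fat_g: 20.2020202
  kcal: 666.6666667
- start_h: 56.0
  duration_min: 15.0
  carb_g: 75.7575758
  protein_g: 45.4545455
  fat_g: 20.2020202
  kcal: 666.6666667
- start_h: 61.0
  duration_min: 15.0
  carb_g: 75.7575758
  protein_g: 45.4545455
  fat_g: 20.2020202
  kcal: 666.6666667
- start_h: 67.0
  duration_min: 15.0
  carb_g: 75.7575758
  protein_g: 45.4545455
  fat_g: 20.2020202
  kcal: 666.6666667
- start_h: 71.0
  duration_min: 10.0
  carb_g: 2.6
  protein_g: 25.55
  fat_g: 2.2111111
  kcal: 132.5
- start_h: 119.0
  duration_min: 10.0
  carb_g: 2.6
  protein_g: 25.55
  fat_g: 2.2111111
  kcal: 132.5
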