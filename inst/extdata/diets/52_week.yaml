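scheme: '5:2'
meals:
- start_h: 8.0
  duration_min: 15.0
  carb_g: 96.969697
  protein_g: 58.1818182
  fat_g: 25.8585859
  kcal: 853.3333333
- start_h: 13.0
  duration_min: 15.0
  carb_g: 96.969697
  protein_g: 58.1818182
  fat_g: 25.8585859
  kcal: 853.3333333
- start_h: 19.0
  duration_min: 15.0
  carb_g: 96.969697
  protein_g: 58.1818182
  fat_g: 25.8585859
  kcal: 853.3333333
- start_h: 32.0
  duration_min: 15.0
  carb_g: 96.969697
  protein_g: 58.1818182
  fat_g: 25.8585859
  kcal: 853.3333333
- start_h: 37.0
  duration_min: 15.0
  carb_g: 96.969697
  protein_g: 58.1818182
  fat_g: 25.8585859
  kcal: 853.3333333
- start_h: 43.0
  duration_min: 15.0
  carb_g: 96.969697
  protein_g: 58.1818182
  fat_g: 25.8585859
  kcal: 853.3333333
- start_h: 56.0
  duration_min: 15.0
  carb_g: 96.969697
  protein_g: 58.1818182
  fat_g: 25.8585859
  kcal: 853.3333333
- start_h: 61.0
  duration_min: 15.0
  carb_g: 96.969697
  protein_g: 58.1818182
  fat_g: 25.8585859
  kcal: 853.3333333
- start_h: 67.0
  duration_min: 15.0
  carb_g: 96.969697
  protein_g: 58.1818182
  fat_g: 25.8585859
  kcal: 853.3333333
- start_h: 80.0
  duration_min: 15.0
  carb_g: 96.969697
  protein_g: 58.1818182
  fat_g: 25.8585859
  kcal: 853.3333333
- start_h: 85.0
  duration_min: 15.0
  carb_g: 96.969697
  protein_g: 58.1818182
  fat_g: 25.8585859
  kcal: 853.3333333
- start_h: 91.0
  duration_min: 15.0
  carb_g: 96.969697
  protein_g: 58.1818182
  fat_g: 25.8585859
  kcal: 853.3333333
- start_h: 104.0
  duration_min: 15.0
  carb_g: 96.969697
  protein_g: 58.1818182
  fat_g: 25.8585859
  kcal: 853.3333333
- start_h: 109.0
  duration_min: 15.0
  carb_g: 96.969697
  protein_g: 58.1818182
  fat_g: 25.8585859
  kcal: 853.3333333
- start_h: 115.0
  duration_min: 15.0
  carb_g: 96.969697
  protein_g: 58.1818182
  fat_g: 25.8585859
  kcal: 853.3333333
- start_h: 132.0
  duration_min: 15.0
  carb_g: 34.0909091
  protein_g: 20.4545455
  fat_g: 9.0909091
  kcal: 300.0
- start_h: 139.0
  duration_min: 15.0
  carb_g: 34.0909091
  protein_g: 20.4545455
  fat_g: 9.0909091
  kcal: 300.0
- start_h: 156.0
  duration_min: 15.0
  carb_g: 34.0909091
  protein_g: 20.4545455
  fat_g: 9.0909091
  kcal: 300.0
- start_h: 163.0
  duration_min: 15.0
  carb_g: 34.0909091
  protein_g: 20.4545455
  fat_g: 9.0909091
  kcal: 300.0
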