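sex: male
weight_kg: 80
height_m: 1.80
age_y: 35
diabetes: false
baselines:
  glucose: 5.0
  insulin: 40
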