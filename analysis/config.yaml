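cohort:
  'n': 49
  age_range:
  - 21.0
  - 83.0
  n_female: 27
noise_frac: 0.05
seed: 927
layout:
  grid_dim:
  - 24
  - 24
  - 24
  cube: 3
metrics:
  n_dirs: 100
  b_values:
  - 700.0
  - 1000.0
  - 1600.0
  s0: 1000.0
  r2star_baseline: 20.0
selection:
  candidates:
  - '1'
  - '2'
  - '3'
  - '1,2'
  - '1,3'
  - '1,2,3'
  prune: yes
associations:
  n_boot: 5000
  p_adjust: holm
output_dir: ~
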