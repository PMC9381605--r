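# Small end-to-end demo: 6-case cohort on a coarse grid.
seed: 4
cohort:
  n_rec: 3
  n_occ: 3
  noise_sd: 1
  grid_shape: [32, 32, 8]
  voxel_spacing: [4, 4, 5]
deconv:
  svd_truncation_fraction: 0.1
  density_constant: 1.05
  hematocrit_factor: 0.73
evaluation:
  grid_style: inhouse
  map_mode: sampled
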