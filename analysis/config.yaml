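# Default run configuration for the analysis stages. Every key shown here
# is optional; unset keys fall back to the same values. Unknown keys are
# rejected by the loader.
seed: 1
cohort:
  n_subjects: 45
  n_timepoints: 160
  voxels_per_network: 40
  grid_shape: [20, 20, 20]
outcome:
  # the five thalamus-involving pairs: SMIxTHA DMNxTHA PMNxTHA VANxTHA MTLxTHA
  active_features: [28, 64, 74, 104, 113]
  weights: [1.0, 0.9, 0.85, 0.8, 0.7]
  link: sigmoid
  gain: 4
  base: 2
  span: 20
  noise_sd: auto
  floor: 0.5
  event_rate: 1
  os_gap_mean: 6
  os_event_rate: 0.8
selection:
  k: 15
  scheme: difference
model:
  widths: [5, 10]
  losses: [mse]
  restarts: 5
  max_iter: 150
augmentation:
  timepoint_fraction_range: [0.70, 0.80]
  voxel_fraction_range: [0.70, 0.80]
  n_augmented_range: [10, 500]
  val_fraction_range: [0.05, 0.20]
clip_cap: 24
paths:
  results_dir: results
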