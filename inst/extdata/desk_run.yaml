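# Example desk-scale pipeline configuration for `msdaspnet run` /
# run_pipeline(); keys mirror the package's constructor arguments.
n_patients: 4
seed: 2
stages: [phantom, prep, train, evaluate]
phantom:
  shape: [24, 128, 128]
  lesion_count: 3
  lesion_radius_range: [4.0, 7.0]
  lesion_contrast: 1.6
  noise_sigma: 2.0
  bias_amplitude: 0.1
preprocess:
  target_size: [128, 128]
slice_filter:
  min_lesion_pixels: 5
  central_band_fraction: 0.7
model:
  profile: desk
train:
  epochs: 10
  test_fraction: 0.25
  freeze_epochs: 0
  max_steps: 60
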