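# Desk-scale pipeline configuration: 4 phantom cases, 32^3 reconstruction.
# Full-scale runs raise phantom.n_cases, gan.volume_size (128) and
# gan.n_epochs; the layout is identical.
seed: 1
out_dir: pipeline_out
phantom:
  n_cases: 4
  volume_shape: 64
  voxel_size_mm: 1
  n_vertebrae_range: [2, 4]
  noise_sd: 20
  arch_enabled: true
drr:
  # six-point opacity transfer function: (normalized intensity, opacity)
  tf_points:
    - [0.00, 0.00]
    - [0.10, 0.00]
    - [0.30, 0.02]
    - [0.55, 0.10]
    - [0.75, 0.35]
    - [1.00, 0.85]
  intensity_scale: 2500
  image_size: 128
  step_mm: 1
preprocess:
  out_size: 128
split:
  train_frac: 0.8
gan:
  volume_size: 32
  base_channels: 4
  n_epochs: 2
  learning_rate: 0.002
  beta1: 0.5
  beta2: 0.99
  loss_weights: {gan: 0.1, recon: 10, proj: 10, fm: 10, idt: 5}
  checkpoint_every: 0
  augment: true
metrics:
  max_intensity: 2500
  ssim_win: 11
  angles: [90, 85, 80, 75]
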