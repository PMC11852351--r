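# Desk-scale profile: 96^3 phantoms, patch 32^3, batch 4, 300 iterations
# on one CPU. Widths are reduced and the learning rate raised to 1e-3 so
# the short schedule converges; see the methods vignette for rationale.
phantom:
  volume_shape: [96, 96, 96]
  spacing: [0.5, 0.5, 0.5]
  n_vessels: 3
  vessel_radius_range: [0.6, 1.2]
  n_aneurysms: 1
  aneurysm_diameter_range: [3, 6]
  vessel_intensity_range: [1600, 2400]
  background_intensity_range: [0, 800]
  noise_sigma: 50
network:
  in_channels: 1
  num_classes: 2
  semantic_widths: [4, 8, 16]
  detail_width: 4
  dam_kernels: [1, 3, 5, 7]
  enable_detail_branch: true
  enable_cfm: true
  enable_dam: true
  enable_deep_supervision: true
  patch_size: 32
train:
  lr0: 3.0e-3
  total_iterations: 300
  batch_size: 4
  patch_size: 32
  fg_bias: 0.5
  augment: true
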