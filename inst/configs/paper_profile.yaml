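# Full-scale training profile: patch 64^3, batch 4, Adam 1e-4 with
# polynomial decay, reference channel widths (1.45 MB float32 storage).
# Intended for real DSA volumes; not exercised by the test suite.
network:
  in_channels: 1
  num_classes: 2
  semantic_widths: [12, 24, 49]
  detail_width: 12
  dam_kernels: [1, 3, 5, 7]
  enable_detail_branch: true
  enable_cfm: true
  enable_dam: true
  enable_deep_supervision: true
  patch_size: 64
train:
  lr0: 1.0e-4
  total_iterations: 25000   # ~100 epochs of 250 sampled batches
  batch_size: 4
  patch_size: 64
  fg_bias: 0.5
  augment: true
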