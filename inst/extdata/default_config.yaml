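# Canonical configuration: published architecture and training protocol.
network:
  input_size: 512
  stem_channels: 32
  stem_stages: 2
  dropout_rate: 0.25
  n_rise_blocks: 6
  block_channels: [32, 64, 128, 256, 256, 256]
  se_ratio: 8
  use_se: true
  use_skip: true
  use_inception: true
  n_classes: 4
  n_severities: 3
  dense_units: 512
training:
  learning_rate: 1.0e-5
  epochs: 100
  batch_size: 8
  n_folds: 5
  seed: 1
  task: classification
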