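# Example vqcbench pipeline configuration. Unknown sections or keys are
# rejected, so typos fail loudly.
cohort:
  n_records: 918
  target_prevalence: 0.55
  seed: 1
train:
  seed: 1
  max_epochs: 80
  batches: 5
  batch_size: 64
  lr_patience: 20
  stop_patience: 50
qnn:
  encoding: angle
  layers: 2
  reuploading: false
  dropout: false
grid:
  repeats: 3
  max_configs: 4
  seed: 1
study:
  fractions: [0.1, 0.3, 0.5, 0.7, 1.0]
  repeats: 3
  seed: 1
  qnn_layers: [1, 2]
  include_nn: true
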