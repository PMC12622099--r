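# Example run configuration; every key shown with its default.
# Omitted keys take these defaults; unknown keys are rejected.
data:
  id_column: subject_id
  age_column: age
  label_column: diagnosis
  features: null        # null = every remaining numeric column
  labels: null          # null = labels present in the file
  control_label: CN
model:
  regressor: linear     # linear | ridge | svr
  hyperparams: {}       # e.g. {lambda: 1} for ridge, {cost: 1, epsilon: 0.1} for svr
  n_folds: 5
  bias_method: invert   # invert | residual
mi:
  k_neighbors: 3
seeds:
  master: 42
  n_repeats: 5
output:
  directory: .
  plots: true
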