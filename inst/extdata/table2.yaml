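# Canonical hyperparameter registry: one entry per benchmarked model.
# kNN and DT are cross-validation tuned at fit time; the values here pin
# the search (kNN k searched over k_range, DT over tuneLength complexity
# candidates). All other models use these values directly.
kNN:
  k: 20
  k_range: [5, 45]
DT:
  cp: 0.01
  tuneLength: 10
RF:
  mtry: 3
  ntree: 500
NNet:
  init_rand_weight: 0.5
  decay: 5.0e-4
  max_iteration: 5000
  activation: ReLU
NNet-ML:
  hidden_layer_num: 8
  max_step: 100000
  learning_rate: 0.1
  threshold: 0.01
  activation: ReLU
SVM:
  kernel: radial
  gamma: 0.1
  cost: 1
XGBTree:
  learning_rate: 0.01
  max_depth: 5
  gamma: 3
  nrounds: 150
XGBTree-Grid:
  learning_rate: 0.1
  max_depth: 7
  gamma: 5
  nrounds: 150
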