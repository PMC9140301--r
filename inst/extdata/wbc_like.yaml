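# Default synthetic-data specification: a Wisconsin-like ordinal table.
# Nine 1-10 cytology-style features, ~65:35 benign:malignant imbalance,
# benign class-conditional locations low (< 2.5) and malignant high,
# one strongly rank-correlated pair (cell size/shape, Spearman rho 0.91)
# and two weakly informative features with class-independent distributions.
n_total: 682
imbalance_ratio: 0.5395
correlated_pair:
  a: Cell_Size
  b: Cell_Shape
  rho: 0.91
weak_features: [Clump_Thickness, Mitoses]
seed: 1
round_to_ordinal: true
range: [1, 10]
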