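# enus — engineered up-sampling for imbalanced binary classification

Clinical tabular datasets are routinely imbalanced: the class a model most
needs to catch (the disease) is the rare one, and classifiers trained on
the raw data buy overall accuracy by sacrificing sensitivity. `enus`
implements **engineered up-sampling (ENUS)**, a SMOTE-family method that
balances the *training* partition by synthesizing minority-class records,
together with the complete comparative-evaluation harness needed to
quantify what balancing buys: confusion-matrix metrics, eight classifier
adapters, significance tests, imbalance-ratio sweeps, a feature-importance
frequency ensemble, and a seeded generator of Wisconsin-breast-cancer-like
ordinal data so everything is testable fully offline.

## The method

Let the training set contain m minority records. Until the classes have
equal counts, each synthesis step:

1. draws a **centroid** x<sup>(c)</sup> uniformly from the original
   minority records (it is an existing record, not a cluster mean);
2. finds its k nearest minority neighbours (Euclidean distance over the
   raw ordinal features, ties broken by record order; k = 5 by default,
   effective k = min(k, m − 1));
3. picks one neighbour x<sup>(n)</sup> (uniformly among the k by default,
   or strictly the nearest);
4. sets, independently for every feature f with u_f ~ U[0, 1),

   x̃_f = x<sup>(c)</sup>_f + u_f · (x<sup>(n)</sup>_f − x<sup>(c)</sup>_f)

so every synthetic value lies in the closed interval between its parents
(feature-wise convex envelope). The validation partition is never touched.
A duplication baseline (`duplicate_balance()`) resamples minority records
with replacement instead. Per synthetic record the neighbour scan costs
exactly d·(m − 1) elementary feature differences plus one partial sort —
the package instruments this count and its tests assert it.

Metrics follow the standard definitions with the minority class positive:
Acc = (TP+TN)/(P+N), bAcc = (TPR+TNR)/2, Sen = TP/(TP+FN),
Spe = TN/(TN+FP), Pre = TP/(TP+FP), F1 = 2·Pre·Sen/(Pre+Sen).

## Worked example

```r
library(enus)

ds <- generate_synthetic_dataset(synthetic_spec(seed = 1))
ds
#> <enus_dataset> 682 records, 9 features (Clump_Thickness, Cell_Size, ...)
#>   classes: B=443 / M=239 (positive = M)

# engineer a 10% minority:majority subset, as in an imbalance sweep
sub <- make_ratio_subset(ds, 0.10, seed = 1)
class_counts(sub)
#>   B   M
#> 443  45

# one trial: stratified 80/20 split, ENUS-balance the training part (BN),
# fit gradient-boosted trees, evaluate on the held-out 20%
bn <- run_trial(sub, "XGBTree", "BN", seed = 1)
on <- run_trial(sub, "XGBTree", "ON", seed = 1)   # same split, no balancing
bn$metrics
#> acc=95.92%  bacc=82.77%  sen=66.67%  spe=98.88%  pre=85.71%  f1=75.00%
on$metrics
#> acc=95.92%  bacc=77.78%  sen=55.56%  spe=100.00%  pre=100.00%  f1=71.43%
bn$train_counts
#>   B   M
#> 354 354
```

On the same split and the same model, balancing lifted sensitivity from
55.6% to 66.7% (one more of the nine held-out minority cases caught) at
the price of one false positive — the trade a screening model wants.
Accuracy is unchanged, which is exactly why balanced accuracy and
sensitivity, not plain accuracy, are the headline metrics under
imbalance. Run `run_repeated_experiment()` for means over many re-split
trials with Welch t-tests, and `ratio_sweep()` to repeat the contrast
across imbalance ratios.

The correlation screen flags the engineered collinear pair (the `*Y`
training configurations drop one member before fitting):

```r
spearman_matrix(ds)$flagged
#>   feature_a  feature_b       rho       p_value
#> 1 Cell_Size Cell_Shape 0.9100366 2.903603e-262
```

Reading the real Wisconsin file, when you have it, is one call:
`drop_incomplete(parse_wbc_file("breast-cancer-wisconsin.data"))`.

## Command line

```sh
inst/cli/enus synth --n 700 --ratio 0.35 --seed 1 --out synth.csv
inst/cli/enus balance --input synth.csv --k 5 --seed 42 --output balanced.csv --trace trace.json
inst/cli/enus evaluate --data synth.csv --models RF,XGBTree --configs BN,ON --trials 20 --seed 7 --out results/
```

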