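---
title: "Engineered up-sampling: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engineered up-sampling: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Binary clinical classifiers trained on imbalanced data trade sensitivity
for accuracy: with 65% benign and 35% malignant records a model can look
excellent while missing the cases that matter, and at 5–20% minority share
the effect is severe. `enus` balances the *training* partition by
synthesizing minority records in feature space and ships the evaluation
harness needed to measure, honestly, what that buys.

## The sampler

One synthesis step draws a random minority record (the *centroid* — an
existing record, not a cluster mean), scans the original minority records
of the training set for its k nearest neighbours, picks one, and
interpolates every feature between centroid and neighbour with an
independent uniform weight in [0, 1). Steps repeat until the class counts
are equal. Three points in the method's verbal description are genuinely
ambiguous, and the package resolves each explicitly:

* **Which neighbour?** k neighbours are found but interpolation is against
  "its nearest neighbour". Default `neighbor_choice = "uniform-among-k"`
  draws one of the k uniformly per synthesis (the SMOTE convention, and
  the only reading that makes selecting k > 1 neighbours meaningful);
  `"strict-nearest"` is available and always uses the single nearest.
* **One random weight or one per feature?** The description applies the
  multiply-and-add rule feature by feature, so the weight is drawn
  *independently per feature*. Either way every synthetic value lies in
  the closed interval between its parents; the per-feature variant fills
  the axis-aligned bounding box rather than the connecting segment.
* **What is k?** Never stated. The default is 5, the long-standing SMOTE
  convention, logged in the synthesis trace; the effective neighbourhood
  is min(k, m − 1) for m minority records.

Further fixed conventions: distances are Euclidean over raw ordinal
values (all features share the 1–10 range, so no scaling); distance ties
break by record order, making neighbour lists deterministic; neighbours
are always sought among the *original* minority records, never previously
synthesized ones; synthetic ids are namespaced `synthetic-<n>`; values
stay continuous by default (`round_to_ordinal` exists because the method's
illustration does not resolve it); a lone minority record falls back to
duplication. `clip_to_range` is a guard only — interpolation between
in-range endpoints cannot leave the range.

**Cost accounting.** Each synthesis spends exactly d·(m − 1) elementary
feature-difference operations on the distance scan plus one partial sort
of m − 1 distances; `enus_balance()` counts these and the tests assert the
count. For n syntheses this is O(n·(d·m + m log m)) total. (The method's
published total of O(n·d·m²·log m) does not follow from its own
per-example accounting; the package asserts the derivation, not the
printed total.)

## Metrics

`metric_set()` computes Acc, bAcc, Sen, Spe, Pre and F1 as proportions;
the reporting layer formats percentages. Zero-denominator policy: Sen,
Spe, Pre are 0 when their denominator is 0, and F1 is 0 when
Pre + Sen = 0 — the all-negative classifier scores Sen 0, Spe 1,
bAcc 0.5, not an error. bAcc = (Sen + Spe)/2 and the F1 harmonic-mean
identity are asserted to machine precision on fuzzed tables.

## The classifier adapters

No modelling package of the usual stack is available at build time, so
the learners are self-contained behind a uniform fit/predict adapter;
their hyperparameters are pinned by the packaged `table2.yaml` registry.
Numerical choices that matter:

* **Trees (DT/RF/boosting)** share one exact-greedy Rcpp tree builder with
  two split criteria: count-scaled Gini impurity reduction
  (classification) and the second-order gain with L2 penalty λ = 1 and
  minimum-loss-reduction γ (boosting). Ties in gain keep the first
  candidate in scan order; thresholds are midpoints between distinct
  values.
* **DT** grows with Gini and a complexity parameter cp: a split must
  reduce root-scaled impurity by cp. cp is selected by 10-fold
  cross-validated accuracy over 10 log-spaced candidates
  (10^−4 … 10^−0.5), the registry's `tuneLength = 10`. Importance is mean
  decrease in impurity.
* **RF**: 500 bootstrap trees, mtry = 3 features per split drawn through
  R's RNG (reproducible under the seed), grown to purity; prediction
  averages leaf class proportions (equivalent to vote-majority for pure
  leaves).
* **Gradient-boosted trees** (`XGBTree`): logistic loss, base score at the
  log odds, learning rate 0.01, depth 5, γ = 3. The round count is not
  part of the published configuration; the package fixes `nrounds = 150`
  (the default search maximum of the common training front end) — note
  that 150 × 0.01 of shrinkage keeps this model anchored near the base
  rate, which is precisely why it is the model balancing helps most.
  `XGBTree-Grid` uses the grid's final values (lr 0.1, depth 7, γ = 5) as
  fixed hyperparameters.
* **SVM**: radial kernel trained by sequential minimal optimisation with
  a deterministic max-|E_i − E_j| second-choice heuristic — no random
  working-set selection, so fits are reproducible without a seed.
  Features are centred/scaled on the training set, the convention of the
  usual radial-SVM front ends, so γ = 0.1 acts on comparable coordinates.
  `svm_grid_search()` reproduces the published search: γ ∈ [0, 0.25],
  cost ∈ [0.5, 8], radial kernel, scored by *training-set* accuracy, first
  maximiser in grid order wins; the grid step is not published, so the
  default is 5 points per axis (logged). A cross-validated variant was
  considered and deliberately not made the default, to stay faithful.
* **Neural nets**: the published zero-hidden-layer network with a ReLU
  label reduces, as a function, to logistic regression; it is trained as
  such by full-batch resilient backpropagation with weight decay 5 × 10⁻⁴
  and uniform(±0.5) initialisation ("init_rand_weight = 0.5" is read as
  the half-width of the init range). `NNet-ML` adds one hidden layer of 8
  ReLU units ("hidden_layer_num = 8" read as 8 units in the one added
  layer), stopping when the largest partial derivative falls below 0.01.
  Inputs are min-max scaled internally for stability.
* **kNN** is backed by the FNN package; k is chosen by 10-fold
  cross-validated accuracy over 5, 7, …, 45 (odd values avoid vote ties).

kNN, SVM and the neural nets carry no per-feature attribution; their
importance is tagged `uniform` and they are excluded from the importance
ensemble, mirroring the protocol's removal of k-NN from that analysis.
Tree importances are normalised to sum to one before ranking.

## Statistics

* **Model comparison** uses the *Welch* unequal-variance t-test by
  default: the protocol says only "independent t-test", and run-to-run
  variance differs across models, so the unpooled variant is the safe
  reading (a pooled flag exists). Two constant equal samples give t = 0,
  p = 1. Raw p-values are reported without multiplicity correction,
  matching the published tables; a Holm option would be a one-liner for
  users who want it.
* **Correlation screening** is Spearman (the ordinal features are far
  from normal), average ranks for ties, pairs flagged at |ρ| ≥ 0.9.
  p-values use the t approximation; for n ≤ 7 an exact permutation null
  is enumerated (the n! tables are instant there; the exact branch at
  n = 8–10 would cost 10!·pairs and is not worth it).

## Experiment design

Each trial: stratified 80/20 split → optional removal of the designated
collinear feature (`*Y`) → optional ENUS balancing of the training
partition only (`B*`) → fit (CV tuning inside the training split only) →
one evaluation on the untouched validation split. Within a trial, every
model and configuration shares the same split, so balanced-vs-original
contrasts are paired; per-(model, config) randomness derives from hashed
sub-seeds, so adding a model never perturbs another's stream. Stratified
allocation uses largest-remainder rounding per class (9 records at 3:6
and fraction 0.8 give a 7-record training set with 2 minority members);
ratio subsets use the ceiling rule, the smallest minority count achieving
the requested ratio (23 = ⌈444 × 0.05⌉). The full protocol runs 100
trials; the package default is the desk-scale 20.

## The synthetic world

`generate_synthetic_dataset()` emulates the *described structure* of the
motivating cytology data, not its true joint distribution: nine ordinal
1–10 features; a 443:239 (≈65:35) imbalance via the ceiling rule; benign
class-conditional locations below 2.5 and malignant above 3.0 (per-feature
defaults follow the well-known per-class statistics of the real features);
one engineered pair with Spearman ρ calibrated to 0.91 *on the drawn
sample* by bisecting a Gaussian-copula mixing weight after truncation and
rounding; two weak features with class-independent distributions; a shared
within-class severity factor (latent ρ 0.4) reproducing the strong mutual
feature correlations of the real data; and a 15% borderline fraction of
minority records with locations halfway to the benign class, standing in
for the low-grade/ambiguous lesions that make real minorities hard.
Marginals are inverse-CDF truncated normals driven by standard-normal
latents, so copula dependence survives the map; the analytic mean of the
rounded truncated normal (`truncated_ordinal_mean()`) serves as the
oracle for generator checks. Everything is deterministic under the spec
seed.

What a green test on this world establishes is the *mechanics*: counts,
envelopes, determinism, metric identities, and the direction of the
balancing effect. It does not establish clinical performance numbers —
those depend on the real data file, which cannot be redistributed here
(a structurally matched synthetic replica, clearly labelled, exercises
the parsing/cleaning pipeline's 698 → 682, 443/239 accounting).

## A deliberately red property

The directional acceptance property asks that, at minority:majority ratio
0.10 over 20 paired trials, ENUS raise mean validation sensitivity with a
significant sign test for both gradient-boosted trees *and* the random
forest. The boosted model passes decisively (mean Sen ≈ 0.87 vs 0.74
without balancing; 15 wins, 0 losses). The random forest does not: in
this world its raw-data sensitivity is already ≈ 0.88 at ratio 0.10, and
inspection of per-record vote fractions shows balancing shifts them
upward on average but almost never across the 0.5 threshold, so paired
trials tie and the sign test cannot reach significance. The published
large forest gains at small ratios evidently reflect minority structure
harder than a truncated-Gaussian-copula world produces. The assertion is
kept as specified and left failing rather than quietly reshaping the
generator around it; treat it as a caveat on transferring the method's
reported forest gains to easier data.

## Limitations

* Binary targets only; no ROC/AUC; no under-sampling or SMOTE-variant
  zoo; no categorical-feature distances.
* The self-contained learners are faithful to the pinned
  hyperparameters but are not drop-in re-implementations of caret /
  randomForest / xgboost / kernlab internals; exact published performance
  tables are out of reach by construction (external data, 100 stochastic
  trials) and are not asserted.
* Training runtimes are recorded per trial but never asserted — they are
  hardware facts, not contracts.
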