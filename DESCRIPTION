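Package: enus
Title: Engineered Up-Sampling for Imbalanced Binary Classification
Version: 1.0.0
Author: ENUS package authors
Maintainer: ENUS package authors <enus@localhost>
Description: Balances imbalanced binary classification data by engineered
    up-sampling (ENUS): synthetic minority records are generated by
    interpolating, feature by feature with independent uniform weights,
    between a randomly chosen minority record (the centroid) and one of its
    k nearest minority neighbours, until the two classes have equal counts.
    Ships a full comparative-evaluation harness for the method: readers for
    the Wisconsin breast-cancer file dialect, confusion-matrix metrics
    (accuracy, balanced accuracy, sensitivity, specificity, precision, F1),
    eight classifier adapters with self-contained tree, boosting, SVM and
    neural-network learners, Spearman correlation screening, Welch t-tests,
    repeated-trial experiment orchestration with ratio sweeps and a
    feature-importance frequency ensemble, and a seeded generator of
    Wisconsin-like ordinal synthetic data for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    FNN,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
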