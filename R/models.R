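#' Model identifiers of the evaluation harness
#'
#' The eight benchmarked classifiers: k nearest neighbours, a CART decision
#' tree, a random forest, neural nets with zero and one hidden layer, a
#' radial-kernel SVM, and gradient-boosted trees with fixed and
#' grid-derived hyperparameters.
#' @export
MODEL_IDS <- c("kNN", "DT", "RF", "NNet", "NNet-ML", "SVM", "XGBTree",
               "XGBTree-Grid")

.model_registry <- new.env(parent = emptyenv())

#' Default hyperparameters of a model
#'
#' Read from the packaged `table2.yaml` registry (one entry per model,
#' reproducing the harness's canonical values, e.g. kNN k = 20, RF
#' mtry = 3 / 500 trees, XGBTree learning rate 0.01 / depth 5 / min loss
#' reduction 3). A different registry file can be supplied to re-pin every
#' model at once.
#'
#' @param model_id one of [MODEL_IDS].
#' @param registry path to a YAML registry; default the packaged one.
#' @return named list of hyperparameters.
#' @export
default_hyperparameters <- function(model_id,
                                    registry = system.file(
                                      "extdata", "table2.yaml",
                                      package = "enus")) {
  key <- paste0("reg:", registry)
  if (is.null(.model_registry[[key]]))
    .model_registry[[key]] <- yaml::read_yaml(registry)
  reg <- .model_registry[[key]]
  if (!model_id %in% names(reg)) stop("unknown model_id: ", model_id)
  reg[[model_id]]
}

#' Model configuration
#'
#' @param model_id one of [MODEL_IDS].
#' @param hyperparameters overrides merged over
#'   [default_hyperparameters()].
#' @param cv_folds folds for cross-validated tuning (only kNN and DT tune).
#' @param seed integer seed, or `NULL` to consume the caller's stream.
#' @return list of class `model_config`.
#' @export
model_config <- function(model_id, hyperparameters = list(),
                         cv_folds = 10L, seed = NULL) {
  model_id <- match.arg(model_id, MODEL_IDS)
  hp <- utils::modifyList(default_hyperparameters(model_id),
                          hyperparameters)
  structure(list(model_id = model_id, hyperparameters = hp,
                 cv_folds = as.integer(cv_folds), seed = seed),
            class = "model_config")
}

# cross-validated accuracy of a fit/predict pair over a candidate grid;
# returns the first maximiser (ties favour earlier candidates)
cv_select <- function(x, y, candidates, folds, fit_one, pred_one) {
  fold_id <- cv_folds_assign(y, folds)
  acc <- vapply(seq_along(candidates), function(ci) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- fit_one(x[tr, , drop = FALSE], y[tr], candidates[[ci]])
      ph <- pred_one(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum((ph > 0.5) == (y[!tr] > 0.5))
    }
    correct / length(y)
  }, numeric(1))
  list(best = candidates[[which.max(acc)]], accuracy = acc)
}

#' Fit one of the harness's classifiers
#'
#' Uniform adapter: every model is fitted on the training dataset's feature
#' matrix against the positive (minority) class. Models the harness tunes
#' -- kNN (k searched over 5..45) and DT (10 complexity-parameter
#' candidates) -- are selected by stratified `cv_folds`-fold
#' cross-validated accuracy and refitted on the full training data; the
#' remaining models use their registry hyperparameters directly. The whole
#' fit is deterministic under the config seed.
#'
#' @param config a [model_config()] (or a model id, taken with defaults).
#' @param train training [enus_dataset()] with both classes present.
#' @return list of class `trained_model`: the fitted estimator, schema,
#'   class labels, tuning record and fit wall-time in seconds.
#' @export
fit_model <- function(config, train) {
  if (is.character(config)) config <- model_config(config)
  stopifnot(inherits(config, "model_config"))
  cc <- class_counts(train)
  if (any(cc == 0)) stop("training data must contain both classes")
  folds <- config$cv_folds
  if (min(cc) < folds) {
    folds <- max(2L, min(cc))
    warning(sprintf("reducing cv folds to %d (smallest class has %d records)",
                    folds, min(cc)))
  }
  x <- feature_matrix(train)
  y <- response01(train)
  hp <- config$hyperparameters
  run <- function() {
    tuning <- NULL
    fit <- switch(
      config$model_id,
      "kNN" = {
        ks <- seq(hp$k_range[1], hp$k_range[2], by = 2)
        ks <- ks[ks < length(y)]
        sel <- cv_select(x, y, as.list(ks), folds,
                         function(x, y, k) fit_knn(x, y, k),
                         predict_knn_prob)
        tuning <- list(k = sel$best, candidates = ks,
                       cv_accuracy = sel$accuracy)
        fit_knn(x, y, sel$best)
      },
      "DT" = {
        cps <- 10^seq(-4, -0.5, length.out = hp$tuneLength)
        sel <- cv_select(x, y, as.list(cps), folds,
                         function(x, y, cp) fit_cart(x, y, cp = cp),
                         predict_cart_prob)
        tuning <- list(cp = sel$best, candidates = cps,
                       cv_accuracy = sel$accuracy)
        fit_cart(x, y, cp = sel$best)
      },
      "RF" = fit_rf(x, y, ntree = hp$ntree, mtry = hp$mtry),
      "NNet" = fit_mlp(x, y, hidden = 0L, decay = hp$decay,
                       maxit = hp$max_iteration,
                       init_half_width = hp$init_rand_weight),
      "NNet-ML" = fit_mlp(x, y, hidden = hp$hidden_layer_num,
                          maxit = hp$max_step,
                          threshold = hp$threshold,
                          step0 = hp$learning_rate),
      "SVM" = fit_svm_rbf(x, y, cost = hp$cost, gamma = hp$gamma),
      "XGBTree" = ,
      "XGBTree-Grid" = fit_gbt(x, y, nrounds = hp$nrounds,
                               learning_rate = hp$learning_rate,
                               max_depth = hp$max_depth,
                               gamma = hp$gamma))
    list(fit = fit, tuning = tuning)
  }
  timed <- measure_runtime(function() {
    if (is.null(config$seed)) run() else with_seed(config$seed, run())
  })
  structure(list(model_id = config$model_id, fit = timed$value$fit,
                 tuning = timed$value$tuning,
                 feature_names = train$feature_names,
                 classes = train$classes,
                 positive_class = train$positive_class,
                 config = config,
                 runtime_seconds = timed$seconds),
            class = "trained_model")
}

predict_prob <- function(model, x) {
  switch(model$model_id,
         "kNN" = predict_knn_prob(model$fit, x),
         "DT" = predict_cart_prob(model$fit, x),
         "RF" = predict_rf_prob(model$fit, x),
         "NNet" = , "NNet-ML" = predict_mlp_prob(model$fit, x),
         "SVM" = predict_svm_prob(model$fit, x),
         "XGBTree" = , "XGBTree-Grid" = predict_gbt_prob(model$fit, x))
}

#' Predict class labels
#'
#' Prediction is pure: repeated calls on the same input return identical
#' labels. The dataset's schema must match the training schema exactly
#' (same features, any order).
#'
#' @param model a [fit_model()] result.
#' @param data an [enus_dataset()].
#' @return character vector of labels.
#' @export
predict_labels <- function(model, data) {
  missing <- setdiff(model$feature_names, data$feature_names)
  extra <- setdiff(data$feature_names, model$feature_names)
  if (length(missing) || length(extra))
    stop("schema mismatch; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]")
  if (!n_records(data)) return(character(0))
  x <- feature_matrix(data)[, model$feature_names, drop = FALSE]
  p <- predict_prob(model, x)
  neg <- setdiff(model$classes, model$positive_class)
  ifelse(p > 0.5, model$positive_class, neg)
}

#' Grid search for radial-SVM hyperparameters
#'
#' Fits a radial-kernel SVM on every cell of a cost x gamma grid and scores
#' each fit by *training-set* accuracy (the harness's search procedure does
#' exactly this), returning the first maximising cell in grid order (cost
#' varies fastest). The default search box is gamma in \[0, 0.25\] and cost
#' in \[0.5, 8\].
#'
#' @param train training [enus_dataset()].
#' @param cost_range,gamma_range closed search ranges.
#' @param grid_points points per axis (default 5, i.e. 25 cells).
#' @param seed integer seed (the SMO solver itself is deterministic; the
#'   seed is kept for interface symmetry).
#' @return list with `best` (cost, gamma, accuracy) and `table` (one row
#'   per cell, in grid order).
#' @export
svm_grid_search <- function(train, cost_range = c(0.5, 8),
                            gamma_range = c(0, 0.25), grid_points = 5L,
                            seed = NULL) {
  if (grid_points < 1) stop("grid_points must be >= 1")
  if (diff(range(cost_range)) < 0 || diff(range(gamma_range)) < 0)
    stop("degenerate search ranges")
  axis <- function(r) if (grid_points == 1) mean(r)
                      else seq(r[1], r[2], length.out = grid_points)
  grid <- expand.grid(cost = axis(cost_range), gamma = axis(gamma_range))
  x <- feature_matrix(train)
  y <- response01(train)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    fit <- fit_svm_rbf(x, y, cost = grid$cost[i], gamma = grid$gamma[i])
    mean((svm_decision(fit, x) > 0) == (y > 0.5))
  }, numeric(1))
  best <- which(acc == max(acc))[1]  # first maximiser in grid order
  list(best = list(cost = grid$cost[best], gamma = grid$gamma[best],
                   accuracy = acc[best]),
       table = cbind(grid, accuracy = acc))
}

#' Feature-importance ranking of a fitted model
#'
#' Tree models report mean decrease in impurity (DT, RF) or total split
#' gain (XGBTree variants), normalised to sum to one and sorted
#' non-increasing with ties broken by feature order. Models without a
#' per-feature attribution (kNN, SVM, the neural nets) are tagged
#' `uniform`: every predictor carries equal weight and no ranking
#' positions are assigned, so the frequency ensemble excludes them.
#'
#' @param model a [fit_model()] result.
#' @return list of class `importance_ranking`: `features` (descending
#'   importance), `scores`, `method` tag.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "trained_model")) stop("model is not fitted")
  method <- switch(model$model_id,
                   "DT" = , "RF" = "impurity",
                   "XGBTree" = , "XGBTree-Grid" = "gain",
                   "uniform")
  d <- length(model$feature_names)
  if (method == "uniform") {
    return(structure(list(features = model$feature_names,
                          scores = rep(1 / d, d), method = "uniform"),
                     class = "importance_ranking"))
  }
  raw <- model$fit$importance
  tot <- sum(raw)
  scores <- if (tot > 0) raw / tot else rep(1 / d, d)
  ord <- order(-scores, seq_along(scores))
  structure(list(features = model$feature_names[ord],
                 scores = unname(scores[ord]), method = method),
            class = "importance_ranking")
}
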