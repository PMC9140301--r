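#' The four training configurations
#'
#' Two binary switches applied to the *training* partition only:
#' balanced (`B`, ENUS up-sampling) vs original (`O`) data, crossed with
#' removal (`Y`) vs retention (`N`) of the designated collinear feature.
#' @export
TRAINING_CONFIGS <- c("BN", "BY", "ON", "OY")

#' Deterministic per-trial seed derivation
#'
#' Hashes the base seed with the trial index and the (model, config) key so
#' adding or removing a model never perturbs another model's random
#' streams. Result is a positive integer below 2^31 - 1.
#'
#' @param base_seed experiment-level integer seed.
#' @param trial trial index.
#' @param model_id,config identifying strings.
#' @export
derive_seed <- function(base_seed, trial, model_id = "", config = "") {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(paste(model_id, config, sep = "|")))
    h <- (h * 31 + ch) %% m
  (((base_seed %% m) * 2654435 + trial * 97561 + h) %% (m - 1)) + 1
}

#' Elapsed wall-time of a stage
#'
#' Monotonic-clock seconds around a callable; informational only (training
#' runtimes are reported, never asserted).
#'
#' @param stage a zero-argument function.
#' @return list with `seconds` and the stage's `value`.
#' @export
measure_runtime <- function(stage) {
  t0 <- proc.time()[["elapsed"]]
  value <- stage()
  list(seconds = proc.time()[["elapsed"]] - t0, value = value)
}

#' Run a single train/evaluate trial
#'
#' One pass of the evaluation protocol: stratified 80/20 split, optional
#' collinear-feature removal (`*Y` configs), optional ENUS balancing of the
#' training partition only (`B*` configs), model fitting (with
#' cross-validated tuning where the model calls for it), and a single
#' evaluation on the held-out validation records. Every stochastic step
#' consumes a sub-seed derived from `seed`, so identical calls are
#' identical. Validation ids are asserted disjoint from training ids at
#' the evaluation boundary.
#'
#' @param data cleaned [enus_dataset()] (no missing values).
#' @param model a model id from [MODEL_IDS] or a [model_config()].
#' @param config one of [TRAINING_CONFIGS].
#' @param seed integer trial seed.
#' @param split_fraction training fraction.
#' @param removal_feature feature dropped in `*Y` configs; defaults to
#'   `"Cell_Size"` when present.
#' @param sampler a [sampler_config()] for the `B*` configs.
#' @param trial optional trial index carried into the result.
#' @return list of class `trial_result`: metrics on validation, confusion
#'   counts, importance ranking, per-stage seeds, class counts and fit
#'   runtime.
#' @export
run_trial <- function(data, model, config = "BN", seed = 1L,
                      split_fraction = 0.8, removal_feature = NULL,
                      sampler = sampler_config(), trial = NA_integer_) {
  config <- match.arg(config, TRAINING_CONFIGS)
  if (is.character(model)) model <- model_config(model)
  if (any(is.na(data$x)))
    stop("data must be cleaned (no missing values); see drop_incomplete()")
  if (is.null(removal_feature))
    removal_feature <- if ("Cell_Size" %in% data$feature_names) "Cell_Size"
  # the split depends on the trial seed only: within one trial every model
  # and every training configuration sees the same 80/20 partition, so
  # balanced-vs-original contrasts are paired on a common split
  sp <- stratified_split(data, split_fraction,
                         seed = derive_seed(seed, 1, "", "split"))
  train <- sp$train
  validation <- sp$validation
  if (substr(config, 2, 2) == "Y") {
    if (is.null(removal_feature))
      stop("config ", config, " removes a feature but none is designated")
    train <- drop_feature(train, removal_feature)
    validation <- drop_feature(validation, removal_feature)
  }
  if (substr(config, 1, 1) == "B") {
    sampler$seed <- derive_seed(seed, 2, model$model_id,
                                paste0(config, ":balance"))
    train <- enus_balance(train, sampler)
  }
  stopifnot(length(intersect(sp$train$ids, validation$ids)) == 0)
  model$seed <- derive_seed(seed, 3, model$model_id,
                            paste0(config, ":fit"))
  fitted <- fit_model(model, train)
  pred <- predict_labels(fitted, validation)
  counts <- confusion_counts(validation$y, pred,
                             positive = data$positive_class,
                             classes = data$classes)
  structure(list(trial = trial, seed = seed, config = config,
                 model_id = fitted$model_id,
                 metrics = metric_set(counts), confusion = counts,
                 importance = feature_importance(fitted),
                 tuning = fitted$tuning,
                 runtime_seconds = fitted$runtime_seconds,
                 train_counts = class_counts(train),
                 validation_counts = class_counts(validation)),
            class = "trial_result")
}

metric_names <- c("acc", "bacc", "sen", "spe", "pre", "f1")

#' Aggregate trial results into a summary table
#'
#' @param trials list of [run_trial()] results.
#' @return data.frame with one row per (model, config, metric):
#'   mean, min, max over trials.
#' @export
aggregate_trials <- function(trials) {
  keys <- unique(data.frame(
    model = vapply(trials, `[[`, "", "model_id"),
    config = vapply(trials, `[[`, "", "config"),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- trials[vapply(trials, function(t)
      t$model_id == keys$model[i] && t$config == keys$config[i],
      logical(1))]
    do.call(rbind, lapply(metric_names, function(mn) {
      v <- vapply(sel, function(t) t$metrics[[mn]], numeric(1))
      data.frame(model = keys$model[i], config = keys$config[i],
                 metric = mn, mean = mean(v), min = min(v), max = max(v),
                 n_trials = length(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Repeated-trial comparative experiment
#'
#' Runs `n_trials` independent [run_trial()] calls for every model x
#' training-configuration cell (each trial re-splits the data), aggregates
#' mean/min/max of each metric, tests each model against a reference model
#' (default the gradient-boosted tree) with Welch t-tests on the per-trial
#' metric values pooled across configurations, and tabulates the
#' top-3 feature-importance frequency ensemble.
#'
#' @param data cleaned [enus_dataset()].
#' @param models character ids and/or [model_config()] objects.
#' @param configs subset of [TRAINING_CONFIGS].
#' @param n_trials trials per cell (the full protocol uses 100; desk-scale
#'   runs use 20).
#' @param base_seed experiment seed; per-trial seeds come from
#'   [derive_seed()].
#' @param reference_model id the t-tests compare against, or `NULL`.
#' @param ... passed to [run_trial()].
#' @return list of class `experiment_summary`: `trials`, `summary`,
#'   `ttests`, `importance`.
#' @export
run_repeated_experiment <- function(data, models = c("RF", "XGBTree"),
                                    configs = TRAINING_CONFIGS,
                                    n_trials = 20L, base_seed = 1L,
                                    reference_model = "XGBTree", ...) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  trials <- list()
  for (mo in models) {
    mid <- if (is.character(mo)) mo else mo$model_id
    for (cf in configs) {
      for (tr in seq_len(n_trials)) {
        # one seed per trial index: every model/config cell of trial t
        # shares the same split, while balancing and fitting streams are
        # re-derived per (model, config) inside run_trial
        trials[[length(trials) + 1L]] <-
          run_trial(data, mo, cf,
                    seed = derive_seed(base_seed, tr, "", "trial"),
                    trial = tr, ...)
      }
    }
  }
  model_ids <- vapply(trials, `[[`, "", "model_id")
  ttests <- NULL
  if (!is.null(reference_model) && reference_model %in% model_ids) {
    others <- setdiff(unique(model_ids), reference_model)
    ttests <- do.call(rbind, lapply(others, function(mid) {
      do.call(rbind, lapply(metric_names, function(mn) {
        ref <- vapply(trials[model_ids == reference_model],
                      function(t) t$metrics[[mn]], numeric(1))
        oth <- vapply(trials[model_ids == mid],
                      function(t) t$metrics[[mn]], numeric(1))
        tt <- welch_t_test(ref, oth)
        data.frame(model = mid, metric = mn, t = tt$t, df = tt$df,
                   p_value = tt$p_value, stringsAsFactors = FALSE)
      }))
    }))
  }
  structure(list(trials = trials, summary = aggregate_trials(trials),
                 ttests = ttests,
                 importance = importance_frequency(trials),
                 base_seed = base_seed),
            class = "experiment_summary")
}

#' Top-3 feature-importance frequency ensemble
#'
#' For every model whose trials carry a real (non-uniform) importance
#' ranking, the fraction of trials in which each feature occupied rank 1,
#' 2 or 3. Models tagged `uniform` (kNN, SVM, neural nets) are excluded,
#' mirroring the protocol's removal of k-NN from the importance analysis.
#'
#' @param trials list of [run_trial()] results.
#' @return data.frame of class `importance_summary`: model, feature, rank
#'   (1-3), fraction over that model's included trials.
#' @export
importance_frequency <- function(trials) {
  rankable <- trials[vapply(trials, function(t)
    t$importance$method != "uniform", logical(1))]
  if (!length(rankable)) {
    warning("no rankable trials; returning empty importance summary")
    return(structure(data.frame(model = character(0),
                                feature = character(0),
                                rank = integer(0), fraction = numeric(0)),
                     class = c("importance_summary", "data.frame")))
  }
  mids <- unique(vapply(rankable, `[[`, "", "model_id"))
  out <- do.call(rbind, lapply(mids, function(mid) {
    sel <- rankable[vapply(rankable, function(t) t$model_id == mid,
                           logical(1))]
    feats <- unique(unlist(lapply(sel, function(t) t$importance$features)))
    do.call(rbind, lapply(feats, function(fe) {
      do.call(rbind, lapply(1:3, function(rk) {
        frac <- mean(vapply(sel, function(t)
          length(t$importance$features) >= rk &&
            t$importance$features[rk] == fe, logical(1)))
        data.frame(model = mid, feature = fe, rank = rk, fraction = frac,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(out) <- NULL
  structure(out, class = c("importance_summary", "data.frame"))
}

#' Imbalance-ratio sweep
#'
#' For each requested minority:majority ratio, builds a ratio-controlled
#' subset ([make_ratio_subset()]) and runs a repeated experiment on it,
#' contrasting balanced (`B*`) against original (`O*`) preprocessing.
#' Infeasible ratios are skipped with a warning.
#'
#' @param data cleaned [enus_dataset()].
#' @param ratios ratios in (0, 1], e.g. `seq(0.05, 0.5, by = 0.05)`.
#' @param models,configs,n_trials,base_seed,... as in
#'   [run_repeated_experiment()].
#' @return data.frame: ratio x model x config x metric means, plus a
#'   `summaries` attribute holding each per-ratio `experiment_summary`.
#' @export
ratio_sweep <- function(data, ratios, models = c("RF", "XGBTree"),
                        configs = c("BN", "ON"), n_trials = 20L,
                        base_seed = 1L, ...) {
  rows <- list()
  summaries <- list()
  for (r in ratios) {
    sub <- tryCatch(
      make_ratio_subset(data, r,
                        seed = derive_seed(base_seed, 1, "ratio",
                                           format(r))),
      error = function(e) {
        warning(sprintf("ratio %.3f skipped: %s", r, conditionMessage(e)))
        NULL
      })
    if (is.null(sub)) next
    es <- run_repeated_experiment(
      sub, models = models, configs = configs, n_trials = n_trials,
      base_seed = derive_seed(base_seed, 2, "sweep", format(r)),
      reference_model = NULL, ...)
    summaries[[format(r)]] <- es
    s <- es$summary
    s$ratio <- r
    rows[[length(rows) + 1L]] <- s
  }
  out <- do.call(rbind, rows)
  attr(out, "summaries") <- summaries
  out
}
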