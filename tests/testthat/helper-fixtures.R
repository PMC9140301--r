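# Fixture builders shared across the suite. Everything is generated in
# code; no binary or downloaded data.

# the walkthrough toy: a 7-record training partition with 2 minority (M)
# and 5 majority (B) records on two ordinal features
toy_train <- function() {
  enus_dataset(paste0("r", 1:7),
               data.frame(a = c(1, 2, 3, 8, 2, 7, 8),
                          b = c(2, 1, 2, 3, 3, 8, 9)),
               c("B", "B", "B", "B", "B", "M", "M"),
               positive_class = "M")
}

# the full 9-record toy (3 minority / 6 majority) it was split from
toy_full <- function() {
  enus_dataset(paste0("r", 1:9),
               data.frame(a = c(1, 2, 3, 8, 2, 9, 7, 8, 6),
                          b = c(2, 1, 2, 3, 3, 2, 8, 9, 7)),
               c("B", "B", "B", "B", "B", "B", "M", "M", "M"),
               positive_class = "M")
}

# random imbalanced fixture with integer 1-10 features
random_imbalanced <- function(n_min, n_maj, d = 3, seed = 1) {
  withr::with_seed(seed, {
    n <- n_min + n_maj
    x <- as.data.frame(matrix(sample(1:10, n * d, replace = TRUE), n, d))
    names(x) <- paste0("f", seq_len(d))
    y <- sample(rep(c("B", "M"), c(n_maj, n_min)))
    enus_dataset(paste0("id", seq_len(n)), x, y, positive_class = "M")
  })
}

# cleanly separable two-class data for sanity fits
separable_dataset <- function(n_per_class = 40, seed = 1) {
  withr::with_seed(seed, {
    x <- data.frame(
      f1 = c(rnorm(n_per_class, 2, 0.4), rnorm(n_per_class, 8, 0.4)),
      f2 = c(rnorm(n_per_class, 2, 0.4), rnorm(n_per_class, 8, 0.4)))
    y <- rep(c("B", "M"), each = n_per_class)
    enus_dataset(sprintf("s%d", seq_len(2 * n_per_class)), x, y,
                 positive_class = "M")
  })
}

# brute-force k-nearest-minority oracle mirroring the documented tie rule
# (non-decreasing distance, ties by record order)
oracle_knn <- function(data, centroid_idx, k) {
  min_idx <- setdiff(which(data$y == minority_class(data)), centroid_idx)
  xm <- feature_matrix(data)
  d2 <- vapply(min_idx, function(i)
    sum((xm[i, ] - xm[centroid_idx, ])^2), numeric(1))
  min_idx[order(d2, seq_along(min_idx))][seq_len(min(k, length(min_idx)))]
}

# a fabricated trial_result carrying given metrics / importance ranking
fake_trial <- function(model_id, config, metrics, features = NULL,
                       method = "impurity", trial = 1L) {
  ms <- structure(as.list(metrics), class = "metric_set")
  imp <- structure(list(
    features = features %||% character(0),
    scores = if (is.null(features)) numeric(0)
             else rev(seq_along(features)) / sum(seq_along(features)),
    method = method), class = "importance_ranking")
  structure(list(trial = trial, seed = 0L, config = config,
                 model_id = model_id, metrics = ms, confusion = NULL,
                 importance = imp, tuning = NULL, runtime_seconds = 0,
                 train_counts = NULL, validation_counts = NULL),
            class = "trial_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
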