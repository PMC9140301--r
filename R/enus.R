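#' ENUS sampler configuration
#'
#' Parameters of the engineered up-sampler. `k` is the neighbourhood size;
#' the effective neighbourhood is `min(k, m - 1)` where `m` is the minority
#' count of the training set (the centroid itself is never its own
#' neighbour). The method never states a canonical `k`; the default of 5
#' follows the SMOTE convention and is logged in the synthesis trace.
#'
#' `neighbor_choice` resolves a genuine ambiguity in the method's
#' description: `"uniform-among-k"` (default) draws one neighbour uniformly
#' from the k nearest and interpolates every feature against it;
#' `"strict-nearest"` always uses the single nearest neighbour.
#'
#' @param k neighbour count, at least 1.
#' @param seed integer seed, or `NULL` to consume the caller's RNG stream.
#' @param distance metric name; only `"euclidean"` is implemented.
#' @param clip_to_range clip synthetic values to `range` (a no-op for
#'   interpolation between in-range endpoints, kept as a guard).
#' @param neighbor_choice `"uniform-among-k"` or `"strict-nearest"`.
#' @param fallback policy when the minority class has a single member:
#'   `"duplicate"` (copy it) or `"error"`.
#' @param round_to_ordinal round synthetic values to integers (off by
#'   default: synthetic records stay continuous).
#' @param range ordinal feature range used for clipping.
#' @return a list of class `sampler_config`.
#' @export
sampler_config <- function(k = 5L, seed = NULL, distance = "euclidean",
                           clip_to_range = TRUE,
                           neighbor_choice = c("uniform-among-k",
                                               "strict-nearest"),
                           fallback = c("duplicate", "error"),
                           round_to_ordinal = FALSE,
                           range = c(1, 10)) {
  if (!is.numeric(k) || k < 1) stop("k must be at least 1")
  distance <- match.arg(distance, "euclidean")
  structure(list(k = as.integer(k), seed = seed, distance = distance,
                 clip_to_range = clip_to_range,
                 neighbor_choice = match.arg(neighbor_choice),
                 fallback = match.arg(fallback),
                 round_to_ordinal = round_to_ordinal, range = range),
            class = "sampler_config")
}

#' k nearest minority neighbours of a minority record
#'
#' Brute-force Euclidean scan over the *original* minority records of the
#' training set, excluding the centroid itself. Returns the indices (into
#' the dataset's records) of the `min(k, m - 1)` nearest neighbours in
#' non-decreasing distance order; distance ties are broken by record order,
#' so the result is deterministic.
#'
#' @param data training [enus_dataset()].
#' @param centroid_idx record index of the centroid; must be a minority
#'   record.
#' @param k neighbours requested.
#' @param distance metric name (Euclidean).
#' @return integer vector of record indices, with attribute
#'   `feature_diff_ops` counting the elementary per-feature difference
#'   operations spent (`d * (m - 1)` for a d-feature, m-minority scan).
#' @export
find_k_nearest_minority <- function(data, centroid_idx, k,
                                    distance = "euclidean") {
  min_idx <- which(data$y == minority_class(data))
  if (!centroid_idx %in% min_idx)
    stop("centroid must be a minority-class record")
  if (length(min_idx) < 2)
    stop("minority class has fewer than 2 members; fallback applies")
  others <- setdiff(min_idx, centroid_idx)
  xm <- feature_matrix(data)
  diffs <- xm[others, , drop = FALSE] -
    matrix(xm[centroid_idx, ], length(others), ncol(xm), byrow = TRUE)
  d2 <- rowSums(diffs^2)
  k_eff <- min(as.integer(k), length(others))
  ord <- order(d2, seq_along(others))[seq_len(k_eff)]  # stable tie-break
  out <- others[ord]
  attr(out, "feature_diff_ops") <- length(others) * ncol(xm)
  out
}

# one interpolated record; draws ncol(x) uniforms from the current stream
interpolate_features <- function(centroid, neighbor, config) {
  u <- stats::runif(length(centroid))
  v <- centroid + u * (neighbor - centroid)
  if (config$round_to_ordinal) v <- round(v)
  if (config$clip_to_range)
    v <- pmin(pmax(v, config$range[1]), config$range[2])
  list(values = v, u = u)
}

#' Synthesize one minority record between a centroid and a neighbour
#'
#' For every feature f the synthetic value is
#' `centroid_f + u_f * (neighbor_f - centroid_f)` with `u_f ~ U[0, 1)`
#' drawn independently per feature, so each value lies in the closed
#' interval between the two parent values. The label is the minority class
#' and the id is namespaced (`synthetic-<n>`) to stay disjoint from source
#' ids.
#'
#' @param centroid,neighbor numeric feature vectors sharing the schema.
#' @param config a [sampler_config()].
#' @param id id for the synthetic record.
#' @return list with `values` (named numeric vector) and `trace` (a
#'   synthesis trace: parent ids omitted here, per-feature draws `u`).
#' @export
synthesize_record <- function(centroid, neighbor, config = sampler_config(),
                              id = "synthetic-1") {
  if (length(centroid) != length(neighbor) ||
      !identical(names(centroid), names(neighbor)))
    stop("centroid and neighbour do not share a schema")
  res <- interpolate_features(centroid, neighbor, config)
  names(res$values) <- names(centroid)
  list(values = res$values,
       trace = list(id = id, u = res$u))
}

#' Balance a training set by engineered up-sampling (ENUS)
#'
#' Appends synthetic minority records until the minority count equals the
#' majority count. Each synthesis independently (i) draws a centroid
#' uniformly from the original minority records, (ii) scans the original
#' minority records for its `min(k, m - 1)` nearest neighbours (Euclidean,
#' ties by record order), (iii) picks one neighbour per the configured
#' policy, and (iv) interpolates every feature with an independent
#' `U[0, 1)` weight. Original records are never modified, and only the
#' training partition should ever be passed here -- the validation split is
#' evaluation-only.
#'
#' With a single minority record the `fallback` policy applies
#' (duplication). Neighbour searches use only the original minority
#' records, never previously synthesized ones.
#'
#' @param train training [enus_dataset()] containing both classes.
#' @param config a [sampler_config()].
#' @param trace keep a per-synthesis trace (centroid/neighbour ids,
#'   per-feature uniform draws, resulting values) as the
#'   `synthesis_trace` attribute.
#' @return the balanced [enus_dataset()]; attributes: `synthesis_trace`
#'   (when requested) and `op_counts`, a list with the instrumented count
#'   of per-feature difference operations spent on distance scans and the
#'   closed-form expectation `n_synth * d * (m - 1)`.
#' @export
enus_balance <- function(train, config = sampler_config(), trace = FALSE) {
  cc <- class_counts(train)
  if (any(cc == 0)) stop("training data must contain both classes")
  min_lab <- minority_class(train)
  maj_lab <- majority_class(train)
  m <- sum(train$y == min_lab)
  n_needed <- sum(train$y == maj_lab) - m
  if (n_needed <= 0) return(train)
  if (m == 1 && config$fallback == "error")
    stop("minority class has a single member and fallback = 'error'")

  run <- function() {
    min_idx <- which(train$y == min_lab)
    xm <- feature_matrix(train)
    xm_min <- xm[min_idx, , drop = FALSE]
    d <- ncol(xm)
    k_eff <- min(config$k, m - 1L)
    traces <- if (trace) vector("list", n_needed)
    new_x <- matrix(0, n_needed, d, dimnames = list(NULL, colnames(xm)))
    ops <- 0L
    for (i in seq_len(n_needed)) {
      cl <- sample.int(m, 1L)
      ci <- min_idx[cl]
      if (m == 1) {  # duplication fallback
        vals <- xm[ci, ]
        nb <- ci
        u <- rep(NA_real_, d)
      } else {
        # brute-force scan over the original minority records, excluding
        # the centroid; same metric and tie policy as
        # find_k_nearest_minority(), inlined to avoid per-synthesis
        # container rebuilds
        others <- min_idx[-cl]
        diffs <- xm_min[-cl, , drop = FALSE] -
          matrix(xm[ci, ], m - 1L, d, byrow = TRUE)
        d2 <- rowSums(diffs^2)
        ops <- ops + (m - 1L) * d
        nn <- others[order(d2, seq_along(d2))[seq_len(k_eff)]]
        nb <- if (config$neighbor_choice == "strict-nearest") nn[1]
              else nn[sample.int(length(nn), 1L)]
        res <- interpolate_features(xm[ci, ], xm[nb, ], config)
        vals <- res$values
        u <- res$u
      }
      new_x[i, ] <- vals
      if (trace)
        traces[[i]] <- list(centroid_id = train$ids[ci],
                            neighbor_id = train$ids[nb],
                            u = u, values = vals,
                            id = sprintf("synthetic-%d", i))
    }
    list(x = new_x, traces = traces, ops = ops)
  }
  res <- if (is.null(config$seed)) run() else with_seed(config$seed, run())

  out <- suppressWarnings(enus_dataset(
    c(train$ids, sprintf("synthetic-%d", seq_len(n_needed))),
    rbind(train$x, as.data.frame(res$x)),
    c(train$y, rep(min_lab, n_needed)),
    positive_class = train$positive_class, classes = train$classes,
    provenance = train$provenance))
  if (trace) attr(out, "synthesis_trace") <- res$traces
  attr(out, "op_counts") <- list(
    feature_diff_ops = res$ops,
    expected = if (m > 1) n_needed * ncol(train$x) * (m - 1L) else 0L)
  out
}

#' Balance a training set by random duplication
#'
#' The traditional O(n) baseline: minority records are sampled with
#' replacement and appended verbatim (ids namespaced `duplicate-<n>`)
#' until the classes are balanced.
#'
#' @param train training [enus_dataset()] containing both classes.
#' @param seed integer seed, or `NULL` to use the caller's RNG stream.
#' @export
duplicate_balance <- function(train, seed = NULL) {
  cc <- class_counts(train)
  if (any(cc == 0)) stop("training data must contain both classes")
  min_lab <- minority_class(train)
  min_idx <- which(train$y == min_lab)
  n_needed <- sum(train$y == majority_class(train)) - length(min_idx)
  if (n_needed <= 0) return(train)
  pick <- if (is.null(seed)) sample(min_idx, n_needed, replace = TRUE)
          else with_seed(seed, sample(min_idx, n_needed, replace = TRUE))
  suppressWarnings(enus_dataset(
    c(train$ids, sprintf("duplicate-%d", seq_len(n_needed))),
    rbind(train$x, train$x[pick, , drop = FALSE]),
    c(train$y, rep(min_lab, n_needed)),
    positive_class = train$positive_class, classes = train$classes,
    provenance = train$provenance))
}
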