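#' Spearman correlation matrix with collinearity screening
#'
#' Rank-based correlation (average ranks for ties) between every feature
#' pair, with two-sided p-values; the Pearson coefficient is deliberately
#' not offered because the ordinal 1-10 features are far from normal.
#' Pairs whose absolute rho reaches `flag_threshold` are reported as
#' collinearity candidates (the motivating case is a cell size/shape pair
#' at rho 0.91) so one member can be dropped before modelling.
#'
#' p-values use the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` for
#' n above the exact-enumeration cutoff and an exact permutation null
#' (all n! rank permutations) for tiny n; constant features have undefined
#' rank correlation and are reported as such, not silently zeroed.
#'
#' @param data an [enus_dataset()]; incomplete records are excluded.
#' @param flag_threshold absolute rho at or above which a pair is flagged.
#' @param exact_n_max largest n for which the permutation null is
#'   enumerated exactly (n! grows fast; 7 keeps it instant).
#' @return list of class `correlation_matrix`: `rho`, `p` (matrices),
#'   `method`, `n`, `flagged` (data.frame), `undefined` (feature names).
#' @export
spearman_matrix <- function(data, flag_threshold = 0.9, exact_n_max = 7L) {
  keep <- !apply(is.na(data$x), 1L, any)
  x <- as.matrix(data$x[keep, , drop = FALSE])
  n <- nrow(x)
  if (n < 3) stop("need at least 3 complete records")
  d <- ncol(x)
  constant <- apply(x, 2, function(v) length(unique(v)) == 1)
  r <- apply(x, 2, rank)  # average ranks for ties
  rho <- suppressWarnings(stats::cor(r))
  diag(rho) <- 1
  rho[constant, ] <- NA; rho[, constant] <- NA
  diag(rho) <- ifelse(constant, NA, 1)

  pval_t <- function(rh) {
    tt <- rh * sqrt((n - 2) / pmax(1 - rh^2, .Machine$double.eps))
    2 * stats::pt(-abs(tt), n - 2)
  }
  p <- matrix(NA_real_, d, d, dimnames = dimnames(rho))
  if (n <= exact_n_max) {
    perms <- all_permutations(n)
    for (i in seq_len(d - 1)) for (j in (i + 1):d) {
      if (is.na(rho[i, j])) next
      ra <- r[, i] - mean(r[, i]); rb <- r[, j] - mean(r[, j])
      obs <- sum(ra * rb)
      null <- as.vector(matrix(rb[perms], nrow(perms)) %*% ra)
      p[i, j] <- p[j, i] <- mean(abs(null) >= abs(obs) - 1e-12)
    }
  } else {
    p[] <- pval_t(rho)
  }
  diag(p) <- ifelse(constant, NA, 0)

  pairs <- which(upper.tri(rho) & abs(rho) >= flag_threshold, arr.ind = TRUE)
  flagged <- data.frame(
    feature_a = colnames(x)[pairs[, 1]],
    feature_b = colnames(x)[pairs[, 2]],
    rho = rho[pairs], p_value = p[pairs],
    stringsAsFactors = FALSE)
  structure(list(rho = rho, p = p, method = "spearman", n = n,
                 flagged = flagged,
                 undefined = colnames(x)[constant]),
            class = "correlation_matrix")
}

# all permutations of 1..n as an n!-row matrix (recursive construction)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Independent two-sample t-test (Welch)
#'
#' Compares repeated-trial metric samples of two models. The
#' unequal-variance (Welch) statistic with Welch-Satterthwaite degrees of
#' freedom is the default, since run-to-run variance differs across
#' models; a pooled-variance variant is available. Degenerate inputs are
#' resolved explicitly: two constant equal samples give t = 0, p = 1;
#' constant samples with different means give p = 0.
#'
#' @param a,b numeric samples, each of size at least 2.
#' @param conf confidence level.
#' @param pooled use the pooled-variance (classic) statistic.
#' @return list of class `ttest_result`: `t`, `df`, `p_value`,
#'   `conf_level`, `mean_a`, `mean_b`, `conf_int`.
#' @export
welch_t_test <- function(a, b, conf = 0.95, pooled = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    delta <- mean(a) - mean(b)
    return(structure(list(
      t = if (delta == 0) 0 else sign(delta) * Inf,
      df = length(a) + length(b) - 2,
      p_value = if (delta == 0) 1 else 0,
      conf_level = conf, mean_a = mean(a), mean_b = mean(b),
      conf_int = c(delta, delta)), class = "ttest_result"))
  }
  ht <- stats::t.test(a, b, var.equal = pooled, conf.level = conf)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, conf_level = conf,
                 mean_a = mean(a), mean_b = mean(b),
                 conf_int = unname(ht$conf.int)),
            class = "ttest_result")
}
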