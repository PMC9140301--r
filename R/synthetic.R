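#' Specification for a Wisconsin-like synthetic dataset
#'
#' Describes the structural features the generator emulates from the real
#' cytology data: nine ordinal 1-10 features, a roughly 65:35
#' benign:malignant imbalance (tunable down to 5:100), class-conditional
#' mean separation (benign locations below 2.5, malignant above 3.0), one
#' strongly rank-correlated feature pair (cell size/shape, target Spearman
#' rho 0.91), and weakly informative features whose class-conditional
#' distributions coincide (clump thickness / mitoses analogues).
#'
#' Locations/scales parameterise latent normals truncated to `range`;
#' because of truncation and rounding the realised class-conditional means
#' differ slightly from the latent locations (see
#' [truncated_ordinal_mean()] for the exact value).
#'
#' @param n_total total record count (majority + minority, ceiling rule).
#' @param imbalance_ratio minority/majority count ratio in (0, 1].
#' @param feature_names feature columns to generate.
#' @param location_negative,location_positive named per-feature latent
#'   locations for the negative (benign) and positive (malignant) class.
#'   Weak features must be given identical values in both.
#' @param scale_negative,scale_positive named per-feature latent standard
#'   deviations.
#' @param correlated_pair list with `a`, `b`, `rho`: feature `b` is coupled
#'   to `a` through a shared latent component calibrated at generation time
#'   so the empirical Spearman rho of the pair matches `rho`.
#' @param weak_features features generated independently of the class.
#' @param common_factor_rho latent within-class correlation shared by all
#'   informative features (a single "disease severity" factor), emulating
#'   the real data's strong mutual feature correlations; weak features stay
#'   independent of it.
#' @param borderline_fraction fraction of minority records drawn as
#'   borderline cases, with informative-feature locations halfway between
#'   the malignant and benign values. Emulates the low-grade/ambiguous
#'   lesions of real cytology data that sit near the class boundary; these
#'   are the cases a majority-biased classifier misses, and the reason
#'   boundary-generalising up-sampling helps at small imbalance ratios.
#' @param seed integer seed; the whole draw is seed-deterministic.
#' @param round_to_ordinal round values to integers (default) or keep
#'   continuous.
#' @param range closed feature range.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_total = 682,
                           imbalance_ratio = 239 / 443,
                           feature_names = wbc_schema()$feature_names,
                           location_negative = NULL,
                           location_positive = NULL,
                           scale_negative = NULL,
                           scale_positive = NULL,
                           correlated_pair = list(a = "Cell_Size",
                                                  b = "Cell_Shape",
                                                  rho = 0.91),
                           weak_features = c("Clump_Thickness", "Mitoses"),
                           common_factor_rho = 0.4,
                           borderline_fraction = 0.15,
                           seed = 1L,
                           round_to_ordinal = TRUE,
                           range = c(1, 10)) {
  d <- length(feature_names)
  fill <- function(x, default) {
    out <- stats::setNames(rep(default, d), feature_names)
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  # Default class-conditional latent parameters approximate the well-known
  # per-class statistics of the real cytology features: benign locations
  # low (<= 2.5), malignant locations high (>= 3.0) with much larger
  # spread, so the classes overlap realistically instead of separating
  # perfectly. Unknown feature names fall back to the generic low/high
  # pattern.
  wbc_loc_neg <- c(Clump_Thickness = 4.0, Cell_Size = 1.6,
                   Cell_Shape = 1.7, Adhesion = 1.5, Epi_Cell_Size = 2.1,
                   Nuclei = 1.4, Chromatin = 2.1, Nucleoli = 1.3,
                   Mitoses = 1.5)
  wbc_loc_pos <- c(Clump_Thickness = 4.0, Cell_Size = 6.6,
                   Cell_Shape = 6.6, Adhesion = 4.7, Epi_Cell_Size = 5.3,
                   Nuclei = 7.6, Chromatin = 6.0, Nucleoli = 5.9,
                   Mitoses = 1.5)
  wbc_sc_neg <- c(Clump_Thickness = 2.5, Cell_Size = 1.0,
                  Cell_Shape = 1.2, Adhesion = 1.0, Epi_Cell_Size = 0.9,
                  Nuclei = 1.2, Chromatin = 1.1, Nucleoli = 1.0,
                  Mitoses = 1.0)
  wbc_sc_pos <- c(Clump_Thickness = 2.5, Cell_Size = 2.7,
                  Cell_Shape = 2.6, Adhesion = 3.0, Epi_Cell_Size = 2.4,
                  Nuclei = 3.1, Chromatin = 2.3, Nucleoli = 3.3,
                  Mitoses = 1.0)
  known <- intersect(feature_names, names(wbc_loc_neg))
  loc_neg <- fill(NULL, 2.0); loc_neg[known] <- wbc_loc_neg[known]
  loc_pos <- fill(NULL, 6.5); loc_pos[known] <- wbc_loc_pos[known]
  sc_neg <- fill(NULL, 1.2); sc_neg[known] <- wbc_sc_neg[known]
  sc_pos <- fill(NULL, 2.2); sc_pos[known] <- wbc_sc_pos[known]
  if (!is.null(location_negative)) loc_neg[names(location_negative)] <- location_negative
  if (!is.null(location_positive)) loc_pos[names(location_positive)] <- location_positive
  if (!is.null(scale_negative)) sc_neg[names(scale_negative)] <- scale_negative
  if (!is.null(scale_positive)) sc_pos[names(scale_positive)] <- scale_positive
  loc_pos[weak_features] <- loc_neg[weak_features]
  sc_pos[weak_features] <- sc_neg[weak_features]
  if (imbalance_ratio <= 0 || imbalance_ratio > 1)
    stop("imbalance_ratio must lie in (0, 1]")
  if (!is.null(correlated_pair)) {
    stopifnot(all(c(correlated_pair$a, correlated_pair$b) %in% feature_names),
              abs(correlated_pair$rho) <= 1)
  }
  if (any(loc_neg < range[1] | loc_neg > range[2]) ||
      any(loc_pos < range[1] | loc_pos > range[2]))
    stop("locations must fall inside the feature range")
  structure(list(n_total = n_total, imbalance_ratio = imbalance_ratio,
                 feature_names = feature_names,
                 location_negative = loc_neg, location_positive = loc_pos,
                 scale_negative = sc_neg, scale_positive = sc_pos,
                 correlated_pair = correlated_pair,
                 weak_features = weak_features,
                 common_factor_rho = common_factor_rho,
                 borderline_fraction = borderline_fraction, seed = seed,
                 round_to_ordinal = round_to_ordinal, range = range),
            class = "synthetic_spec")
}

#' Load a synthetic-data specification from YAML
#'
#' The packaged `wbc_like.yaml` reproduces [synthetic_spec()]'s defaults.
#'
#' @param path YAML file; keys mirror [synthetic_spec()] arguments.
#' @export
read_synthetic_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$correlated_pair <- if (!is.null(cfg$correlated_pair))
    list(a = cfg$correlated_pair$a, b = cfg$correlated_pair$b,
         rho = cfg$correlated_pair$rho)
  do.call(synthetic_spec, cfg[!vapply(cfg, is.null, logical(1))])
}

# inverse-CDF draw from a normal truncated to [lo, hi], driven by a
# standard-normal latent so a Gaussian-copula dependence survives the map
truncnorm_from_latent <- function(z, mean, sd, lo, hi) {
  fa <- stats::pnorm(lo, mean, sd)
  fb <- stats::pnorm(hi, mean, sd)
  u <- stats::pnorm(z)
  stats::qnorm(fa + u * (fb - fa), mean, sd)
}

#' Exact mean of a rounded truncated normal on an ordinal range
#'
#' The closed-form expectation of the generator's per-feature marginal:
#' a normal(`mean`, `sd`) truncated to `[lo, hi]` and (optionally) rounded
#' to the nearest integer. Used as the analytic oracle for
#' law-of-large-numbers checks on the generator.
#'
#' @param mean,sd latent normal parameters.
#' @param lo,hi truncation bounds.
#' @param rounded if `TRUE`, expectation of the integer-rounded value.
#' @export
truncated_ordinal_mean <- function(mean, sd, lo = 1, hi = 10,
                                   rounded = TRUE) {
  fa <- stats::pnorm(lo, mean, sd)
  fb <- stats::pnorm(hi, mean, sd)
  if (!rounded) {
    # E[X | lo < X < hi] for X ~ N(mean, sd)
    a <- (lo - mean) / sd
    b <- (hi - mean) / sd
    return(mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
             (stats::pnorm(b) - stats::pnorm(a)))
  }
  vals <- seq(ceiling(lo), floor(hi))
  cuts <- c(lo, utils::head(vals, -1) + 0.5, hi)
  pr <- (stats::pnorm(cuts[-1], mean, sd) -
           stats::pnorm(cuts[-length(cuts)], mean, sd)) / (fb - fa)
  sum(vals * pr)
}

#' Generate a synthetic Wisconsin-like dataset
#'
#' Draws class labels by the ceiling rule (minority count =
#' `ceiling(ratio * majority)`, majority chosen so the total is as close to
#' `n_total` as the rule permits), then feature values through a Gaussian
#' copula: per-record standard-normal latents, the correlated pair coupled
#' through a shared component whose mixing weight is calibrated by
#' bisection *on the drawn sample* until the empirical Spearman rho of the
#' transformed pair hits the target, then an inverse-CDF map onto a
#' truncated normal in `range`, optional integer rounding, and clipping.
#' The same spec and seed give byte-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return an [enus_dataset()] with labels `B`/`M`, positive class `M`.
#' @export
generate_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_total < 10) stop("n_total must be at least 10")
  r <- spec$imbalance_ratio
  n_maj <- floor(spec$n_total / (1 + r))
  while (n_maj + ceiling(r * n_maj) > spec$n_total) n_maj <- n_maj - 1
  while ((n_maj + 1) + ceiling(r * (n_maj + 1)) <= spec$n_total)
    n_maj <- n_maj + 1
  n_min <- as.integer(ceiling(r * n_maj))
  n <- n_maj + n_min
  d <- length(spec$feature_names)
  lo <- spec$range[1]; hi <- spec$range[2]

  with_seed(spec$seed, {
    y <- sample(rep(c("B", "M"), c(n_maj, n_min)))
    z <- matrix(stats::rnorm(n * d), n, d,
                dimnames = list(NULL, spec$feature_names))
    # one shared severity factor couples the informative features
    rho0 <- spec$common_factor_rho
    if (!is.null(rho0) && rho0 > 0) {
      z0 <- stats::rnorm(n)
      informative <- setdiff(spec$feature_names, spec$weak_features)
      z[, informative] <- sqrt(rho0) * z0 +
        sqrt(1 - rho0) * z[, informative]
    }
    pos <- y == "M"
    bf <- spec$borderline_fraction
    borderline <- pos & stats::runif(n) < (if (is.null(bf)) 0 else bf)

    transform <- function(zcol, f) {
      loc <- ifelse(pos, spec$location_positive[f],
                    spec$location_negative[f])
      loc[borderline] <- (spec$location_positive[f] +
                            spec$location_negative[f]) / 2
      sd <- ifelse(pos, spec$scale_positive[f], spec$scale_negative[f])
      v <- truncnorm_from_latent(zcol, loc, sd, lo, hi)
      if (spec$round_to_ordinal) v <- round(v)
      pmin(pmax(v, lo), hi)
    }

    x <- matrix(0, n, d, dimnames = list(NULL, spec$feature_names))
    for (f in spec$feature_names) x[, f] <- transform(z[, f], f)

    cp <- spec$correlated_pair
    if (!is.null(cp)) {
      za <- z[, cp$a]
      eb <- z[, cp$b]
      mix <- function(w) transform(w * za + sqrt(1 - w^2) * eb, cp$b)
      emp_rho <- function(w)
        stats::cor(x[, cp$a], mix(w), method = "spearman")
      # bisection on the mixing weight against the realised Spearman rho
      wl <- 0; wh <- 0.99999
      if (emp_rho(wh) < cp$rho) {
        w <- wh
      } else {
        for (it in 1:30) {
          w <- (wl + wh) / 2
          if (emp_rho(w) < cp$rho) wl <- w else wh <- w
        }
        w <- (wl + wh) / 2
      }
      x[, cp$b] <- mix(w)
    }
  })

  suppressWarnings(enus_dataset(
    sprintf("synth-%d", seq_len(n)), as.data.frame(x), y,
    positive_class = "M", classes = c("B", "M"),
    provenance = sprintf("synthetic wbc-like (seed %d)", spec$seed)))
}

#' Write a synthetic replica of the Wisconsin source file
#'
#' Emits a headerless 11-column comma-separated file in the Wisconsin
#' dialect built from [generate_synthetic_dataset()] output: integer sample
#' codes, nine ordinal features, numeric class codes (2 = benign, 4 =
#' malignant), with a chosen number of records given a `?` in the bare
#' nuclei column. This is a *synthetic stand-in* for the UCI file (which
#' cannot be redistributed here), structured to exercise the same parsing
#' and cleaning path: by default 698 rows of which 16 are incomplete and
#' the 682 complete rows split 443 benign / 239 malignant.
#'
#' @param path output file.
#' @param n_complete_negative,n_complete_positive complete-record class
#'   counts.
#' @param n_missing rows given a missing bare-nuclei value.
#' @param seed integer seed.
#' @return the path, invisibly.
#' @export
write_synthetic_wbc_file <- function(path,
                                     n_complete_negative = 443,
                                     n_complete_positive = 239,
                                     n_missing = 16,
                                     seed = 1L) {
  n_total <- n_complete_negative + n_complete_positive + n_missing
  spec <- synthetic_spec(
    n_total = 2 * n_total,  # generous pool; rows are drawn per class below
    imbalance_ratio = 0.999, seed = seed)
  pool <- generate_synthetic_dataset(spec)
  with_seed(seed + 1L, {
    neg <- sample(which(pool$y == "B"), n_complete_negative + n_missing)
    pos <- sample(which(pool$y == "M"), n_complete_positive)
    idx <- sample(c(neg, pos))
    ds <- dataset_subset(pool, idx)
    m <- feature_matrix(ds)
    # the incomplete rows come out of the negative surplus so the complete
    # remainder has exactly the requested per-class counts
    rows_missing <- sample(which(ds$y == "B"), n_missing)
    lines <- vapply(seq_len(nrow(m)), function(i) {
      feats <- format(m[i, ], trim = TRUE)
      if (i %in% rows_missing) feats[["Nuclei"]] <- "?"
      paste(c(1000000 + i, feats, if (ds$y[i] == "B") 2 else 4),
            collapse = ",")
    }, character(1))
  })
  writeLines(lines, path)
  invisible(path)
}
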