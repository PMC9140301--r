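#' Confusion-matrix tallies
#'
#' Exact TP/TN/FP/FN counts with the designated positive (minority,
#' disease) class. Sensitivity is then the ability to detect the disease
#' when present; specificity the ability to rule it out when absent.
#'
#' @param truth,predicted equal-length label vectors drawn from the two
#'   schema classes.
#' @param positive the positive-class label.
#' @param classes optional length-2 label set for validation; inferred
#'   from the inputs when omitted.
#' @return list of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted, positive, classes = NULL) {
  if (length(truth) != length(predicted) || length(truth) < 1)
    stop("truth and predicted must have equal length >= 1")
  if (is.null(classes)) {
    classes <- unique(c(truth, predicted, positive))
    if (length(classes) > 2)
      stop("more than two distinct labels: ",
           paste(classes, collapse = ", "))
  } else {
    bad <- setdiff(unique(c(truth, predicted)), classes)
    if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
    if (!positive %in% classes) stop("positive label not in class set")
  }
  tpos <- truth == positive
  ppos <- predicted == positive
  structure(list(tp = sum(tpos & ppos), tn = sum(!tpos & !ppos),
                 fp = sum(!tpos & ppos), fn = sum(tpos & !ppos)),
            class = "confusion_counts")
}

#' The six evaluation metrics from confusion counts
#'
#' Computes, as proportions in \[0, 1\]:
#' \deqn{Acc = (TP+TN)/(P+N)}
#' \deqn{bAcc = (TPR+TNR)/2}
#' \deqn{Sen = TP/(TP+FN), \quad Spe = TN/(TN+FP)}
#' \deqn{Pre = TP/(TP+FP), \quad F1 = 2 \cdot Pre \cdot Sen/(Pre+Sen)}
#' Zero-denominator convention: Sen, Spe and Pre are 0 when their
#' denominator is 0, and F1 is 0 when Pre + Sen = 0. Formatting as
#' percentages is left to the reporting layer.
#'
#' @param counts a [confusion_counts()] (or list with tp/tn/fp/fn).
#' @return named list of class `metric_set`: `acc`, `bacc`, `sen`, `spe`,
#'   `pre`, `f1`.
#' @export
metric_set <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total < 1) stop("all-zero confusion counts")
  safe_div <- function(num, den) if (den > 0) num / den else 0
  sen <- safe_div(tp, tp + fn)
  spe <- safe_div(tn, tn + fp)
  pre <- safe_div(tp, tp + fp)
  structure(list(
    acc = (tp + tn) / total,
    bacc = (sen + spe) / 2,
    sen = sen, spe = spe, pre = pre,
    f1 = if (pre + sen > 0) 2 * pre * sen / (pre + sen) else 0),
    class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 4, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%s=%.*f%%", names(v), pmax(digits - 2, 0), 100 * v),
            collapse = "  "), "\n")
  invisible(x)
}

#' One-call evaluation of predictions
#'
#' @param truth,predicted label vectors.
#' @param positive positive-class label.
#' @return a [metric_set()].
#' @export
evaluate_predictions <- function(truth, predicted, positive) {
  metric_set(confusion_counts(truth, predicted, positive))
}
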