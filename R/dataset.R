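#' Construct a tabular classification dataset
#'
#' The package's central container: an ordered collection of records, each
#' with an opaque id, a fixed set of numeric (for the Wisconsin dialect,
#' ordinal 1-10) feature values that may be missing, and one of two class
#' labels. One label is designated the *positive* class; by the package's
#' convention this is the minority / disease class (malignant, "M") and all
#' sensitivity-style metrics and the up-samplers treat it as such.
#'
#' @param ids character vector of record identifiers. Duplicates are allowed
#'   (the UCI Wisconsin file repeats sample codes) but raise a warning.
#' @param x data.frame or matrix of numeric feature values, `NA` = missing.
#' @param y character vector of class labels, exactly two distinct values
#'   across `y` and `classes`.
#' @param positive_class the label treated as positive/minority.
#' @param classes optional length-2 character vector fixing the label set
#'   (negative first); inferred from `y` and `positive_class` if omitted.
#' @param provenance free-text origin note carried along by transformations.
#' @return an object of class `enus_dataset`.
#' @export
enus_dataset <- function(ids, x, y, positive_class, classes = NULL,
                         provenance = "") {
  x <- as.data.frame(x)
  ids <- as.character(ids)
  y <- as.character(y)
  stopifnot(length(ids) == nrow(x), length(y) == nrow(x))
  if (is.null(classes)) {
    classes <- union(unique(y), positive_class)
    classes <- c(setdiff(classes, positive_class), positive_class)
  }
  if (length(classes) != 2L)
    stop("a dataset must have exactly two classes, got: ",
         paste(classes, collapse = ", "))
  if (!positive_class %in% classes)
    stop("positive_class '", positive_class, "' is not one of the classes")
  bad <- setdiff(unique(y), classes)
  if (length(bad))
    stop("labels outside the class set: ", paste(bad, collapse = ", "))
  if (anyDuplicated(ids))
    warning("duplicate record ids present (allowed, but flagged)")
  rownames(x) <- NULL
  structure(
    list(ids = ids, x = x, y = y,
         feature_names = colnames(x),
         positive_class = positive_class,
         classes = classes,
         provenance = provenance),
    class = "enus_dataset")
}

#' @export
print.enus_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf(
    "<enus_dataset> %d records, %d features (%s)\n", n_records(x),
    length(x$feature_names), paste(x$feature_names, collapse = ", ")))
  cat(sprintf("  classes: %s=%d / %s=%d (positive = %s)\n",
              names(cc)[1], cc[1], names(cc)[2], cc[2], x$positive_class))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of records in a dataset
#' @param data an `enus_dataset`.
#' @export
n_records <- function(data) length(data$ids)

#' Per-class record counts
#'
#' @param data an `enus_dataset`.
#' @return named integer vector in class order (negative class first).
#' @export
class_counts <- function(data) {
  vapply(data$classes, function(cl) sum(data$y == cl), integer(1))
}

#' Labels of the minority (positive) and majority (negative) classes
#' @param data an `enus_dataset`.
#' @export
minority_class <- function(data) data$positive_class

#' @rdname minority_class
#' @export
majority_class <- function(data) setdiff(data$classes, data$positive_class)

#' Subset a dataset by record index
#' @param data an `enus_dataset`.
#' @param idx integer or logical index into the records.
#' @export
dataset_subset <- function(data, idx) {
  enus_dataset(data$ids[idx], data$x[idx, , drop = FALSE], data$y[idx],
               positive_class = data$positive_class, classes = data$classes,
               provenance = data$provenance)
}

#' @export
as.data.frame.enus_dataset <- function(x, ...) {
  cbind(data.frame(id = x$ids, stringsAsFactors = FALSE), x$x,
        data.frame(class = x$y, stringsAsFactors = FALSE))
}

#' Feature matrix of a dataset
#' @param data an `enus_dataset`.
#' @return numeric matrix, one row per record.
#' @export
feature_matrix <- function(data) {
  as.matrix(data$x)
}

# internal: 0/1 response with 1 = positive class
response01 <- function(data) as.numeric(data$y == data$positive_class)
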