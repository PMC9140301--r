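#' Column schema for the Wisconsin breast-cancer file dialect
#'
#' The UCI `breast-cancer-wisconsin.data` dialect: 11 comma-separated
#' columns with no header -- a sample code number, nine ordinal cytology
#' features scored 1-10, and a numeric class code (2 = benign, 4 =
#' malignant) -- with `?` marking a missing value. The mapping lives in this
#' schema object rather than in the parser so any headerless numeric binary
#' table can be read by supplying a different schema.
#'
#' @param feature_names names for the feature columns, in file order.
#' @param class_map named character vector mapping raw class codes to
#'   labels.
#' @param positive_class label of the minority/disease class.
#' @param id_column 1-based index of the identifier column.
#' @param class_column 1-based index of the class column.
#' @param missing_token token denoting a missing value.
#' @param ordinal_range closed range feature values must fall in, or `NULL`
#'   to accept any numeric value.
#' @return a list of class `wbc_schema`.
#' @export
wbc_schema <- function(feature_names = c(
                         "Clump_Thickness", "Cell_Size", "Cell_Shape",
                         "Adhesion", "Epi_Cell_Size", "Nuclei", "Chromatin",
                         "Nucleoli", "Mitoses"),
                       class_map = c("2" = "B", "4" = "M"),
                       positive_class = "M",
                       id_column = 1L,
                       class_column = 11L,
                       missing_token = "?",
                       ordinal_range = c(1, 10)) {
  structure(list(feature_names = feature_names, class_map = class_map,
                 positive_class = positive_class, id_column = id_column,
                 class_column = class_column, missing_token = missing_token,
                 ordinal_range = ordinal_range,
                 n_columns = length(feature_names) + 2L),
            class = "wbc_schema")
}

#' Parse a file in the Wisconsin dialect
#'
#' Reads a headerless comma-separated file, one record per line, validating
#' that every line has exactly the schema's column count and that every
#' non-missing field is numeric. No row is ever dropped silently; cleaning
#' is a separate, reported step ([drop_incomplete()]).
#'
#' @param path file to read.
#' @param schema a [wbc_schema()].
#' @return an [enus_dataset()].
#' @export
parse_wbc_file <- function(path, schema = wbc_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nc <- schema$n_columns
  if (!length(lines)) {
    x <- as.data.frame(matrix(numeric(0), ncol = length(schema$feature_names),
                              dimnames = list(NULL, schema$feature_names)))
    return(enus_dataset(character(0), x, character(0),
                        positive_class = schema$positive_class,
                        classes = unname(c(
                          setdiff(schema$class_map, schema$positive_class),
                          schema$positive_class)),
                        provenance = path))
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  nfields <- lengths(parts)
  if (any(nfields != nc)) {
    bad <- which(nfields != nc)[1]
    stop(sprintf("line %d has %d fields, expected %d", bad, nfields[bad], nc))
  }
  m <- matrix(unlist(parts), nrow = length(lines), ncol = nc, byrow = TRUE)
  m <- trimws(m)
  feat_cols <- setdiff(seq_len(nc), c(schema$id_column, schema$class_column))
  fm <- m[, feat_cols, drop = FALSE]
  fm[fm == schema$missing_token] <- NA
  num <- suppressWarnings(array(as.numeric(fm), dim = dim(fm)))
  bad <- which(is.na(num) & !is.na(fm), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("line %d: non-numeric field '%s' in column %d",
                 bad[1, 1], fm[bad[1, 1], bad[1, 2]], feat_cols[bad[1, 2]]))
  }
  if (!is.null(schema$ordinal_range)) {
    out_of_range <- !is.na(num) &
      (num < schema$ordinal_range[1] | num > schema$ordinal_range[2])
    if (any(out_of_range)) {
      bad <- which(out_of_range, arr.ind = TRUE)[1, ]
      stop(sprintf("line %d: feature value %s outside [%g, %g]",
                   bad[1], num[bad[1], bad[2]],
                   schema$ordinal_range[1], schema$ordinal_range[2]))
    }
  }
  colnames(num) <- schema$feature_names
  raw_class <- m[, schema$class_column]
  unknown <- setdiff(unique(raw_class), names(schema$class_map))
  if (length(unknown)) {
    bad <- which(raw_class == unknown[1])[1]
    stop(sprintf("line %d: unknown class code '%s'", bad, unknown[1]))
  }
  enus_dataset(m[, schema$id_column], as.data.frame(num),
               unname(schema$class_map[raw_class]),
               positive_class = schema$positive_class,
               classes = unname(c(
                 setdiff(schema$class_map, schema$positive_class),
                 schema$positive_class)),
               provenance = path)
}

#' Read / write the headered CSV variant
#'
#' `write_dataset_csv()` emits a headered CSV (id column, features, class
#' column) using the schema's missing token for `NA`, and
#' `read_dataset_csv()` reads it back; the two round-trip every field
#' including missing values.
#'
#' @param data an [enus_dataset()].
#' @param path file to write / read.
#' @param positive_class label of the positive class (read side).
#' @param missing_token token written for / interpreted as missing.
#' @export
write_dataset_csv <- function(data, path, missing_token = "?") {
  df <- as.data.frame(data)
  utils::write.csv(df, path, row.names = FALSE, na = missing_token,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @param id_column,class_column column names in the headered file.
#' @export
read_dataset_csv <- function(path, positive_class = "M", id_column = "id",
                             class_column = "class", missing_token = "?") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = missing_token,
                        colClasses = stats::setNames(
                          c("character", "character"),
                          c(id_column, class_column)))
  feats <- setdiff(names(df), c(id_column, class_column))
  enus_dataset(df[[id_column]], df[feats], df[[class_column]],
               positive_class = positive_class, provenance = path)
}

#' Remove records with missing feature values
#'
#' Returns the complete-case dataset; the removal is reported, never
#' silent. The report (removed ids and count) is attached as the
#' `removal_report` attribute and also available via
#' `attr(result, "removal_report")`.
#'
#' @param data an [enus_dataset()].
#' @return the filtered dataset with a `removal_report` attribute holding
#'   `removed_ids` and `n_removed`.
#' @export
drop_incomplete <- function(data) {
  complete <- !apply(is.na(data$x), 1L, any)
  out <- suppressWarnings(dataset_subset(data, complete))
  attr(out, "removal_report") <- list(
    removed_ids = data$ids[!complete],
    n_removed = sum(!complete))
  out
}

#' Remove one feature from a dataset
#'
#' Used to drop a collinear predictor (the paper-style configurations
#' remove the feature pair member with Spearman rho about 0.9) before
#' model fitting. Record count is unchanged.
#'
#' @param data an [enus_dataset()].
#' @param name feature to remove; must exist.
#' @export
drop_feature <- function(data, name) {
  if (!name %in% data$feature_names)
    stop("unknown feature: ", name)
  suppressWarnings(enus_dataset(
    data$ids, data$x[setdiff(data$feature_names, name)], data$y,
    positive_class = data$positive_class, classes = data$classes,
    provenance = data$provenance))
}

# largest-remainder allocation of a per-class training quota
largest_remainder <- function(counts, fraction) {
  quota <- fraction * counts
  base <- floor(quota)
  total <- floor(sum(quota) + 0.5)
  extra <- total - sum(base)
  if (extra > 0) {
    ord <- order(-(quota - base), seq_along(counts))
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation split
#'
#' Randomly partitions records into a training and a validation dataset,
#' preserving the minority:majority ratio in both. Per-class training
#' counts follow a largest-remainder allocation of `fraction`, so e.g. 9
#' records (3 minority / 6 majority) at 0.8 give a 7-record training set
#' with 2 minority members. Reproducible under `seed`.
#'
#' @param data an [enus_dataset()]; every class needs at least one record.
#' @param fraction training fraction, strictly inside (0, 1).
#' @param seed integer seed.
#' @return list of class `enus_split` with `train`, `validation`,
#'   `split_fraction`, `seed`.
#' @export
stratified_split <- function(data, fraction = 0.8, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly inside (0, 1)")
  cc <- class_counts(data)
  if (any(cc < 1)) stop("every class needs at least one record to split")
  take <- largest_remainder(cc, fraction)
  train_idx <- integer(0)
  with_seed(seed, {
    for (i in seq_along(data$classes)) {
      cl_idx <- which(data$y == data$classes[i])
      train_idx <- c(train_idx, sort(sample(cl_idx, take[i])))
    }
  })
  train_idx <- sort(train_idx)
  val_idx <- setdiff(seq_len(n_records(data)), train_idx)
  structure(list(train = dataset_subset(data, train_idx),
                 validation = dataset_subset(data, val_idx),
                 split_fraction = fraction, seed = seed),
            class = "enus_split")
}

#' Build a ratio-controlled imbalanced subset
#'
#' Keeps every majority-class record and samples, without replacement,
#' `ceiling(ratio * majority_count)` minority records -- the smallest count
#' achieving at least the requested minority:majority ratio (444 majority at
#' ratio 0.05 gives 23 minority). Used for the imbalance-ratio sweep.
#'
#' @param data an [enus_dataset()].
#' @param ratio target minority/majority ratio in (0, 1].
#' @param seed integer seed.
#' @export
make_ratio_subset <- function(data, ratio, seed = 1L) {
  if (!is.numeric(ratio) || ratio <= 0 || ratio > 1)
    stop("ratio must lie in (0, 1]")
  min_idx <- which(data$y == minority_class(data))
  maj_idx <- which(data$y == majority_class(data))
  need <- as.integer(ceiling(ratio * length(maj_idx)))
  if (need > length(min_idx))
    stop(sprintf("infeasible ratio %.3f: need %d minority records, have %d",
                 ratio, need, length(min_idx)))
  keep_min <- with_seed(seed, sample(min_idx, need))
  dataset_subset(data, sort(c(maj_idx, keep_min)))
}

# evaluate expr with a locally seeded RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
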