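#' Construct a feature matrix
#'
#' The container passed between encoders, feature selection and the
#' classifiers: a numeric samples-by-features matrix with unique sample ids
#' (rownames), unique feature names (colnames) and an optional binary label
#' vector aligned to the samples (1 = allergenic, 0 = non-allergenic).
#'
#' @param values Numeric matrix with rownames (sample ids) and colnames
#'   (feature names).
#' @param labels Optional integer vector of 0/1 labels, one per row.
#' @return An object of class `feature_matrix`: a list with elements
#'   `values`, `sample_ids`, `feature_names` and `labels`.
#' @export
feature_matrix <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (sample ids) and colnames (feature names)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ", rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature names: ", colnames(values)[duplicated(colnames(values))][1L])
  if (!all(is.finite(values)))
    stop("feature values must all be finite")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values))
      stop("`labels` length (", length(labels), ") != number of samples (",
           nrow(values), ")")
    if (!all(labels %in% c(0L, 1L)))
      stop("`labels` must be binary 0/1")
  }
  structure(
    list(values = values,
         sample_ids = rownames(values),
         feature_names = colnames(values),
         labels = labels),
    class = "feature_matrix"
  )
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else
                sprintf(" (labels: %d pos / %d neg)",
                        sum(x$labels == 1L), sum(x$labels == 0L))))
  invisible(x)
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

# internal: subset columns by name, preserving the given order
fm_select_columns <- function(fm, cols) {
  missing <- setdiff(cols, fm$feature_names)
  if (length(missing))
    stop("unknown feature names: ", paste(utils::head(missing, 5L), collapse = ", "))
  feature_matrix(fm$values[, cols, drop = FALSE], labels = fm$labels)
}

# internal: subset rows by index
fm_subset_rows <- function(fm, idx) {
  feature_matrix(fm$values[idx, , drop = FALSE],
                 labels = if (is.null(fm$labels)) NULL else fm$labels[idx])
}

#' Write a feature matrix to CSV
#'
#' First column `sample_id`, one column per feature, optional trailing
#' `label` column. Values are written at full precision so that
#' [read_feature_csv()] round-trips ids, names and values exactly.
#'
#' @param fm A [feature_matrix()].
#' @param path Output file path.
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(sample_id = fm$sample_ids, fm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(fm$labels)) df$label <- fm$labels
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' Inverse of [write_feature_csv()].
#'
#' @param path CSV file path.
#' @return A [feature_matrix()].
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("CSV lacks a `sample_id` column")
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  ids <- as.character(df$sample_id)
  df$sample_id <- NULL
  values <- as.matrix(df)
  storage.mode(values) <- "double"
  rownames(values) <- ids
  feature_matrix(values, labels = labels)
}
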