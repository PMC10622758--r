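#' Rank features by Pearson correlation with the class label
#'
#' Computes, for every feature column, the Pearson correlation coefficient
#' (PCC) against the 0/1 label vector — for a binary label this is the
#' point-biserial correlation. Features are ordered by decreasing |PCC|;
#' the signed score is kept for reporting. Constant columns get a score of 0
#' with a warning. Ties are broken by original column index, so the ordering
#' is stable and deterministic.
#'
#' @param fm A labelled [feature_matrix()] with both classes present.
#' @return A `data.frame` of class `feature_ranking` with columns
#'   `feature_name`, `score` and `rank` (1 = strongest |PCC|).
#' @export
rank_by_pcc <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels)) stop("feature matrix has no labels")
  if (length(unique(fm$labels)) < 2L)
    stop("both classes must be present to rank features")
  if (ncol(fm$values) == 0L) stop("feature matrix has no columns")

  scores <- suppressWarnings(
    as.vector(stats::cor(fm$values, as.numeric(fm$labels)))
  )
  constant <- is.na(scores)
  if (any(constant)) {
    warning(sum(constant), " constant feature column(s) assigned PCC 0")
    scores[constant] <- 0
  }
  ord <- order(-abs(scores))  # stable: ties keep original column order
  ranking <- data.frame(feature_name = fm$feature_names[ord],
                        score = scores[ord],
                        rank = seq_along(ord),
                        stringsAsFactors = FALSE)
  class(ranking) <- c("feature_ranking", "data.frame")
  ranking
}

#' Select the top-n ranked features
#'
#' Restricts a feature matrix to the `n` best-ranked columns, in ranking
#' order. The default n = 200 is the pipeline's standard subset size for the
#' 1620-dimensional fused representation.
#'
#' @param ranking A `feature_ranking` from [rank_by_pcc()].
#' @param fm The [feature_matrix()] the ranking was computed on (or one with
#'   the same columns).
#' @param n Number of features to keep.
#' @return A [feature_matrix()] with `n` columns.
#' @export
select_top <- function(ranking, fm, n = 200L) {
  stopifnot(inherits(ranking, "feature_ranking"), inherits(fm, "feature_matrix"))
  n <- as.integer(n)
  if (n < 1L || n > nrow(ranking))
    stop("`n` must be between 1 and the number of ranked features (",
         nrow(ranking), ")")
  fm_select_columns(fm, ranking$feature_name[seq_len(n)])
}

#' Incremental feature selection (IFS) scan
#'
#' Evaluates nested top-n subsets of the PCC ranking: for each n in `grid`
#' the classifier is trained and scored under stratified k-fold
#' cross-validation on the top-n columns, and the mean out-of-fold accuracy
#' is recorded. The ranking is re-fit inside each training fold so the scan
#' itself does not leak label information.
#'
#' @param fm A labelled [feature_matrix()].
#' @param grid Integer vector of subset sizes to evaluate.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed controlling fold assignment and model fitting.
#' @param n_trees Trees for the random-forest evaluator.
#' @return A `data.frame` with columns `n_features` and `accuracy`, with the
#'   selected size (argmax accuracy, ties to the smaller n) in attribute
#'   `best_n`.
#' @export
ifs_scan <- function(fm, grid, folds = 5L, seed = 1L, n_trees = 200L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels)) stop("feature matrix has no labels")
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 1L) || any(grid > ncol(fm$values)))
    stop("grid values must be between 1 and ", ncol(fm$values))

  fold_id <- stratified_folds(fm$labels, folds, seed)
  acc <- vapply(grid, function(n) {
    hits <- 0L
    for (f in seq_len(folds)) {
      train <- fm_subset_rows(fm, fold_id != f)
      test <- fm_subset_rows(fm, fold_id == f)
      sub <- select_top(rank_by_pcc(train), train, n)
      model <- train_rf(sub, n_trees = n_trees, seed = seed + f)
      pred <- predict(model, fm_select_columns(test, sub$feature_names))
      hits <- hits + sum(pred$call == test$labels)
    }
    hits / nrow(fm$values)
  }, numeric(1))
  out <- data.frame(n_features = grid, accuracy = acc)
  attr(out, "best_n") <- grid[which.max(acc)]  # which.max takes first = smallest n
  out
}

#' Fit a PCA reducer
#'
#' Learns a principal-component projection of the (selected) feature matrix.
#' Columns are centred by their training means; no unit-variance rescaling
#' is applied by default because all features live on a common frequency
#' scale and rescaling would amplify near-constant noise columns. The
#' default q = 100 is the pipeline's standard retained dimension.
#'
#' @param fm A [feature_matrix()].
#' @param q Number of principal components to retain
#'   (`q <= min(samples - 1, features)`).
#' @param scale. Logical: also divide columns by their standard deviation.
#' @return An object of class `pca_reducer`: list with `center` (column
#'   means), `scale`, `loadings` (features x q, orthonormal columns),
#'   `explained_variance` (non-increasing, length q), `q` and
#'   `feature_names` (the input contract for [apply_reducer()]).
#' @export
fit_pca <- function(fm, q = 100L, scale. = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  q <- as.integer(q)
  q_max <- min(nrow(fm$values) - 1L, ncol(fm$values))
  if (q < 1L || q > q_max)
    stop("`q` must be between 1 and min(samples - 1, features) = ", q_max)
  pc <- stats::prcomp(fm$values, center = TRUE, scale. = scale., rank. = q)
  structure(
    list(center = pc$center,
         scale = if (isTRUE(scale.)) pc$scale else NULL,
         loadings = pc$rotation[, seq_len(q), drop = FALSE],
         explained_variance = pc$sdev[seq_len(q)]^2,
         q = q,
         feature_names = fm$feature_names),
    class = "pca_reducer"
  )
}

#' @export
print.pca_reducer <- function(x, ...) {
  cat(sprintf("<pca_reducer> %d features -> %d components\n",
              length(x$feature_names), x$q))
  invisible(x)
}

#' Project a feature matrix through a fitted PCA reducer
#'
#' Centres (and optionally scales) the input by the training statistics and
#' projects it onto the retained principal axes. The input must have exactly
#' the reducer's feature columns, in order.
#'
#' @param reducer A `pca_reducer` from [fit_pca()].
#' @param fm A [feature_matrix()] with matching columns.
#' @return A [feature_matrix()] with columns `PC1` ... `PCq`.
#' @export
apply_reducer <- function(reducer, fm) {
  stopifnot(inherits(reducer, "pca_reducer"), inherits(fm, "feature_matrix"))
  if (!identical(fm$feature_names, reducer$feature_names)) {
    missing <- setdiff(reducer$feature_names, fm$feature_names)
    extra <- setdiff(fm$feature_names, reducer$feature_names)
    stop("feature contract violated; missing: [",
         paste(utils::head(missing, 3L), collapse = ", "), "], extra: [",
         paste(utils::head(extra, 3L), collapse = ", "),
         "] (or column order differs)")
  }
  x <- sweep(fm$values, 2L, reducer$center, "-")
  if (!is.null(reducer$scale)) x <- sweep(x, 2L, reducer$scale, "/")
  scores <- x %*% reducer$loadings
  colnames(scores) <- paste0("PC", seq_len(reducer$q))
  feature_matrix(scores, labels = fm$labels)
}
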