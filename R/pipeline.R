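#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow. The defaults are the
#' reference configuration of the method: AAC + DPC + CKSAAP(k = 1, 2, 3)
#' fusion (1620 features), PCC ranking with the top 200 features retained,
#' PCA shrinkage to 100 components, a 200-tree random forest with decision
#' threshold 0.5, stratified 5-fold cross-validation and a stratified 4:1
#' train/validation split.
#'
#' `refit_per_fold = TRUE` (the default) re-fits ranking, selection and PCA
#' inside each training fold so no label information from held-out samples
#' reaches the transform. Setting it to `FALSE` fits them once on the full
#' data handed to [cross_validate()] — a leakier shortcut some published
#' workflows use; it is provided for comparison only.
#'
#' @param encoders Encoder subset, in fusion order.
#' @param gaps CKSAAP gap values.
#' @param n_top Features kept after PCC ranking.
#' @param q_components Principal components retained.
#' @param classifier `"RF"`, `"LR"`, `"SVM"` or `"KNN"`.
#' @param n_trees Random-forest ensemble size.
#' @param threshold Decision threshold.
#' @param folds Cross-validation folds.
#' @param train_fraction Training share of the hold-out split (4:1 = 0.8).
#' @param refit_per_fold Logical leakage switch, see above.
#' @param seed Integer seed for folds, splits and model fitting.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(encoders = c("AAC", "DPC", "CKSAAP"),
                            gaps = c(1L, 2L, 3L),
                            n_top = 200L, q_components = 100L,
                            classifier = c("RF", "LR", "SVM", "KNN"),
                            n_trees = 200L, threshold = 0.5,
                            folds = 5L, train_fraction = 0.8,
                            refit_per_fold = TRUE, seed = 1L) {
  classifier <- match.arg(classifier)
  stopifnot(n_top >= 1L, q_components >= 1L, folds >= 2L,
            train_fraction > 0, train_fraction < 1)
  structure(
    list(encoders = encoders, gaps = as.integer(gaps),
         n_top = as.integer(n_top), q_components = as.integer(q_components),
         classifier = classifier, n_trees = as.integer(n_trees),
         threshold = threshold, folds = as.integer(folds),
         train_fraction = train_fraction,
         refit_per_fold = isTRUE(refit_per_fold), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# internal: fit ranking -> top-n selection -> PCA -> classifier on one
# labelled feature matrix; returns everything needed to score new data
fit_pipeline_on_features <- function(fm, config, seed) {
  n_top <- min(config$n_top, ncol(fm$values))
  q <- min(config$q_components, nrow(fm$values) - 1L, n_top)
  ranking <- rank_by_pcc(fm)
  selected <- select_top(ranking, fm, n_top)
  reducer <- fit_pca(selected, q)
  reduced <- apply_reducer(reducer, selected)
  model <- if (config$classifier == "RF") {
    train_rf(reduced, n_trees = config$n_trees, seed = seed,
             threshold = config$threshold)
  } else {
    train_baseline(reduced, kind = config$classifier, seed = seed,
                   threshold = config$threshold)
  }
  list(ranking = ranking, reducer = reducer, model = model)
}

# internal: score a raw feature matrix through a fitted pipeline
score_pipeline <- function(fitted, fm) {
  selected <- fm_select_columns(fm, fitted$reducer$feature_names)
  predict(fitted$model, apply_reducer(fitted$reducer, selected))
}

#' Train the full pipeline on labelled records
#'
#' Runs encode -> PCC ranking -> top-n selection -> PCA -> classifier on all
#' supplied records and returns the fitted bundle (classifier, reducer,
#' ranking, configuration).
#'
#' @param records Labelled record `data.frame` (see [read_fasta()]).
#' @param config A [pipeline_config()].
#' @return A list of class `aller_pipeline` with elements `model`,
#'   `reducer`, `ranking` and `config`.
#' @export
train_pipeline <- function(records, config = pipeline_config()) {
  fm <- encode_fused(records, config$encoders, config$gaps)
  if (is.null(fm$labels)) stop("records must carry class labels")
  fitted <- fit_pipeline_on_features(fm, config, seed = config$seed)
  structure(c(fitted, list(config = config)), class = "aller_pipeline")
}

#' Score new records with a fitted pipeline
#'
#' @param object An `aller_pipeline` from [train_pipeline()].
#' @param records Record `data.frame` to score (labels ignored).
#' @param ... Unused.
#' @return A `data.frame` with columns `id`, `score` and `call`.
#' @export
predict.aller_pipeline <- function(object, records, ...) {
  fm <- encode_fused(records, object$config$encoders, object$config$gaps)
  score_pipeline(object, fm)
}

#' Stratified k-fold cross-validation of the pipeline
#'
#' Assigns samples to seeded stratified folds; for each fold, the whole
#' transform stack (PCC ranking, top-n selection, PCA) and the classifier
#' are fitted on the training portion only (unless
#' `config$refit_per_fold = FALSE`) and the held-out portion is scored.
#' The pooled report is computed from the concatenated out-of-fold scores;
#' per-fold reports are attached under `$per_fold`.
#'
#' @param records Labelled record `data.frame`.
#' @param config A [pipeline_config()].
#' @return An `evaluation_report` with extra fields `per_fold` (list of
#'   fold reports), `fold_features` (the feature subset each fold's
#'   transform selected — evidence of per-fold refitting) and `scores`
#'   (`data.frame` of `id`, `fold`, `label`, `score`, `call`).
#' @export
cross_validate <- function(records, config = pipeline_config()) {
  fm <- encode_fused(records, config$encoders, config$gaps)
  if (is.null(fm$labels)) stop("records must carry class labels")
  fold_id <- stratified_folds(fm$labels, config$folds, config$seed)

  shared <- if (!config$refit_per_fold)
    fit_pipeline_on_features(fm, config, seed = config$seed)
  scored <- lapply(seq_len(config$folds), function(f) {
    train <- fm_subset_rows(fm, fold_id != f)
    test <- fm_subset_rows(fm, fold_id == f)
    fitted <- if (config$refit_per_fold)
      fit_pipeline_on_features(train, config, seed = config$seed + f)
    else shared
    pred <- score_pipeline(fitted, test)
    list(scores = data.frame(id = pred$id, fold = f, label = test$labels,
                             score = pred$score, call = pred$call,
                             stringsAsFactors = FALSE),
         selected_features = fitted$reducer$feature_names)
  })
  scores <- do.call(rbind, lapply(scored, `[[`, "scores"))

  report <- evaluate_scores(scores$score, scores$label, config$threshold)
  report$per_fold <- lapply(scored, function(s)
    evaluate_scores(s$scores$score, s$scores$label, config$threshold))
  report$fold_features <- lapply(scored, `[[`, "selected_features")
  report$scores <- scores
  report
}

#' Hold-out protocol: stratified 4:1 split, CV on train, final validation
#'
#' Splits the records into stratified training and validation portions
#' (default 4:1), runs [cross_validate()] on the training portion, then fits
#' the pipeline once on the full training portion and evaluates it a single
#' time on the untouched validation portion. Ranking, selection, PCA and the
#' classifier never see validation labels.
#'
#' @param records Labelled record `data.frame`.
#' @param config A [pipeline_config()].
#' @return A list of class `holdout_result`: `training` (CV
#'   `evaluation_report`), `validation` (`evaluation_report`), `pipeline`
#'   (the final fitted `aller_pipeline`) and `split` (logical training
#'   mask).
#' @export
holdout_protocol <- function(records, config = pipeline_config()) {
  if (!"label" %in% names(records) || anyNA(records$label))
    stop("records must carry class labels")
  in_train <- stratified_split(records$label, config$train_fraction,
                               config$seed)
  train_records <- records[in_train, , drop = FALSE]
  valid_records <- records[!in_train, , drop = FALSE]

  training_report <- cross_validate(train_records, config)
  pipeline <- train_pipeline(train_records, config)
  pred <- predict(pipeline, valid_records)
  validation_report <- evaluate_scores(pred$score, valid_records$label,
                                       config$threshold)
  structure(list(training = training_report,
                 validation = validation_report,
                 pipeline = pipeline,
                 split = in_train),
            class = "holdout_result")
}

#' @export
print.holdout_result <- function(x, ...) {
  cat("Training (pooled ", length(x$training$per_fold), "-fold CV):\n",
      sep = "")
  print(x$training)
  cat("Validation (held out):\n")
  print(x$validation)
  invisible(x)
}

#' Tree-count sweep for the random forest
#'
#' Cross-validates the full pipeline for each ensemble size in `grid` and
#' tabulates the pooled metrics, mirroring the standard tree-count
#' comparison (100-500 trees).
#'
#' @param records Labelled record `data.frame`.
#' @param grid Integer vector of ensemble sizes.
#' @param config A [pipeline_config()]; its `n_trees` is overridden.
#' @return A `data.frame` with one row per ensemble size: `n_trees`, `sn`,
#'   `sp`, `precision`, `acc` (percent), `mcc`, `f1`.
#' @export
tree_count_sweep <- function(records, grid = c(100L, 200L, 300L, 400L, 450L, 500L),
                             config = pipeline_config()) {
  do.call(rbind, lapply(as.integer(grid), function(nt) {
    cfg <- config
    cfg$n_trees <- nt
    r <- cross_validate(records, cfg)
    data.frame(n_trees = nt,
               sn = round(100 * r$sn, 1), sp = round(100 * r$sp, 1),
               precision = round(100 * r$precision, 1),
               acc = round(100 * r$acc, 1),
               mcc = round(r$mcc, 2), f1 = round(r$f1, 2))
  }))
}
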