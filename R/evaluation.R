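#' Confusion counts from calls and labels
#'
#' Positives are the allergenic class (label 1).
#'
#' @param calls Integer 0/1 predicted calls.
#' @param labels Integer 0/1 true labels.
#' @return A list with integer fields `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(calls, labels) {
  stopifnot(length(calls) == length(labels),
            all(calls %in% c(0L, 1L)), all(labels %in% c(0L, 1L)))
  list(TP = sum(calls == 1L & labels == 1L),
       FP = sum(calls == 1L & labels == 0L),
       TN = sum(calls == 0L & labels == 0L),
       FN = sum(calls == 0L & labels == 1L))
}

#' Threshold metrics from confusion counts
#'
#' Computes accuracy, sensitivity (recall), specificity, precision, F1 and
#' the Matthews correlation coefficient:
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}{\sqrt{(TP+FP)(TP+FN)(TN+FN)(TN+FP)}}}
#' A zero denominator (e.g. precision when nothing is called positive, or an
#' empty MCC factor) yields 0 with a warning rather than NaN, so report
#' tables stay numeric.
#'
#' @param counts A list with fields `TP`, `FP`, `TN`, `FN`
#'   (see [confusion_counts()]).
#' @return A named list: `acc`, `sn`, `sp`, `precision`, `f1`, `mcc`.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0L) stop("all confusion counts are zero")

  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0")
      return(0)
    }
    num / den
  }
  acc <- (tp + tn) / total
  sn <- safe_div(tp, tp + fn, "sensitivity")
  sp <- safe_div(tn, tn + fp, "specificity")
  precision <- safe_div(tp, tp + fp, "precision")
  f1 <- safe_div(2 * precision * sn, precision + sn, "F1")
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fn, tn + fp)))
  mcc <- safe_div(tp * tn - fp * fn, mcc_den, "MCC")
  list(acc = acc, sn = sn, sp = sp, precision = precision, f1 = f1, mcc = mcc)
}

#' ROC and precision-recall curves
#'
#' Sweeps all distinct score values as thresholds (ties grouped, so samples
#' with equal scores enter the curve together). The AUC is computed by the
#' trapezoid rule on the ROC points and equals the Mann-Whitney concordance
#' probability with the 0.5 tie convention. The AUPRC uses the step-wise
#' average-precision convention (no trapezoid interpolation on PR points,
#' which is known to be optimistic).
#'
#' @param scores Numeric score vector (higher = more allergenic).
#' @param labels Integer 0/1 labels; both classes must be present.
#' @return A list: `roc` (`data.frame` with `threshold`, `fpr`, `tpr`),
#'   `auc`, `pr` (`data.frame` with `threshold`, `recall`, `precision`),
#'   `auprc`.
#' @export
roc_pr_curves <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute ROC/PR curves")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores: last index of each distinct score value
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  cum_tp <- cumsum(y == 1L)[last_of_group]
  cum_fp <- cumsum(y == 0L)[last_of_group]

  tpr <- c(0, cum_tp / n_pos)
  fpr <- c(0, cum_fp / n_neg)
  thr <- c(Inf, s[last_of_group])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)

  recall <- cum_tp / n_pos
  precision <- ifelse(cum_tp + cum_fp > 0, cum_tp / (cum_tp + cum_fp), 0)
  auprc <- sum(diff(c(0, recall)) * precision)

  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc,
       pr = data.frame(threshold = s[last_of_group],
                       recall = recall, precision = precision),
       auprc = auprc)
}

#' Evaluate scored predictions against labels
#'
#' Bundles the threshold metrics (at `threshold`) with ROC/PR curves into a
#' single report.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels Integer 0/1 labels.
#' @param threshold Decision threshold (calls positive at
#'   `score >= threshold`).
#' @return An object of class `evaluation_report`: a list with `counts`,
#'   the scalar metrics of [metrics_from_counts()], `auc`, `auprc`, `roc`,
#'   `pr` and `n`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  calls <- as.integer(scores >= threshold)
  counts <- confusion_counts(calls, labels)
  curves <- roc_pr_curves(scores, labels)
  report <- c(list(counts = counts), metrics_from_counts(counts),
              list(auc = curves$auc, auprc = curves$auprc,
                   roc = curves$roc, pr = curves$pr,
                   n = length(labels)))
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> n=%d  Acc %.1f%%  Sn %.1f%%  Sp %.1f%%  Pre %.1f%%  MCC %.2f  F1 %.2f  AUC %.2f  AUPRC %.2f\n",
    x$n, 100 * x$acc, 100 * x$sn, 100 * x$sp, 100 * x$precision,
    x$mcc, x$f1, x$auc, x$auprc))
  if (!is.null(x$per_fold))
    cat(sprintf("  (%d folds; pooled out-of-fold metrics above)\n",
                length(x$per_fold)))
  invisible(x)
}

#' Report table with one row per metric set
#'
#' Flattens one or more evaluation reports into a `data.frame` with
#' percentages rounded to one decimal (machine-precision values remain in
#' the report objects).
#'
#' @param ... Named `evaluation_report` objects.
#' @return A `data.frame` with columns `dataset`, `sn`, `sp`, `precision`,
#'   `acc` (percent, 1 decimal), `mcc`, `f1`, `auc`, `auprc` (2 decimals).
#' @export
report_table <- function(...) {
  reports <- list(...)
  stopifnot(length(reports) > 0L, !is.null(names(reports)))
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(dataset = nm,
               sn = round(100 * r$sn, 1), sp = round(100 * r$sp, 1),
               precision = round(100 * r$precision, 1),
               acc = round(100 * r$acc, 1),
               mcc = round(r$mcc, 2), f1 = round(r$f1, 2),
               auc = round(r$auc, 2), auprc = round(r$auprc, 2),
               stringsAsFactors = FALSE)
  }))
}

# internal: deterministic stratified fold assignment
stratified_folds <- function(labels, k, seed) {
  k <- as.integer(k)
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < k))
    stop("each class needs at least ", k, " samples for ", k, "-fold CV")
  fold_id <- integer(length(labels))
  set.seed(as.integer(seed))
  for (cl in c(0L, 1L)) {
    idx <- sample(which(labels == cl))
    fold_id[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold_id
}

# internal: deterministic stratified train/validation split
stratified_split <- function(labels, ratio = 0.8, seed = 1L) {
  set.seed(as.integer(seed))
  train <- logical(length(labels))
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    n_train <- round(length(idx) * ratio)
    train[sample(idx, n_train)] <- TRUE
  }
  train
}
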