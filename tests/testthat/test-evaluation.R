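test_that("threshold metrics match hand-computed values", {
  perfect <- metrics_from_counts(list(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(unlist(perfect),
               c(acc = 1, sn = 1, sp = 1, precision = 1, f1 = 1, mcc = 1))

  m <- metrics_from_counts(list(TP = 40, FN = 10, TN = 45, FP = 5))
  expect_equal(m$acc, 0.850)
  expect_equal(m$sn, 0.800)
  expect_equal(m$sp, 0.900)
  expect_equal(m$precision, 40 / 45, tolerance = 1e-12)
  expect_equal(m$f1, 2 * (40 / 45) * 0.8 / ((40 / 45) + 0.8), tolerance = 1e-12)
  expect_equal(m$mcc, (40 * 45 - 5 * 10) / sqrt(45 * 50 * 55 * 50),
               tolerance = 1e-12)
  expect_equal(m$mcc, 0.7035, tolerance = 1e-4)
})

test_that("degenerate confusion counts are handled explicitly", {
  w <- capture_warnings(
    m <- metrics_from_counts(list(TP = 0, FP = 0, TN = 8, FN = 2)))
  expect_match(w, "precision", all = FALSE)
  expect_equal(m$precision, 0)
  expect_equal(m$mcc, 0)
  expect_error(metrics_from_counts(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "all confusion counts are zero")
})

test_that("metrics agree with a brute-force per-sample recount", {
  set.seed(41)
  for (i in 1:10) {
    labels <- rbinom(60, 1, 0.5)
    if (length(unique(labels)) < 2) next
    calls <- rbinom(60, 1, 0.4)
    counts <- confusion_counts(calls, labels)
    expect_equal(counts$TP + counts$FP + counts$TN + counts$FN, 60)
    hits <- sum(calls == labels)
    m <- suppressWarnings(metrics_from_counts(counts))
    expect_equal(m$acc, hits / 60)
    expect_equal(counts$TP, sum(labels[calls == 1] == 1))
    expect_equal(counts$FN, sum(calls[labels == 1] == 0))
  }
})

test_that("MCC is symmetric under simultaneous class/call swap", {
  counts <- list(TP = 31, FP = 9, TN = 44, FN = 16)
  swapped <- list(TP = counts$TN, FP = counts$FN, TN = counts$TP,
                  FN = counts$FP)
  expect_equal(metrics_from_counts(counts)$mcc,
               metrics_from_counts(swapped)$mcc)
})

test_that("ROC/AUC follow the grouped-threshold sweep with trapezoid rule", {
  r <- roc_pr_curves(c(1, 0, 1, 0), c(1L, 0L, 1L, 0L))
  expect_equal(r$auc, 1)
  expect_equal(r$auprc, 1)

  # 4 positive-negative pairs, 3 concordant, 1 discordant
  r <- roc_pr_curves(c(0.9, 0.8, 0.4, 0.3), c(1L, 0L, 1L, 0L))
  expect_equal(r$auc, 0.75)

  r <- roc_pr_curves(rep(0.5, 10), rep(c(0L, 1L), 5))
  expect_equal(r$auc, 0.5)
  expect_equal(r$roc$fpr, c(0, 1))

  expect_error(roc_pr_curves(runif(4), rep(1L, 4)), "both classes")
})

test_that("AUC equals exhaustive pairwise concordance, including ties", {
  set.seed(53)
  for (i in 1:8) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)  # coarse grid forces score ties
    r <- roc_pr_curves(scores, labels)
    expect_equal(r$auc, oracle_auc_pairwise(scores, labels))
  }
})

test_that("curves agree with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(59)
  labels <- rbinom(150, 1, 0.5)
  scores <- runif(150) + 0.5 * labels
  r <- roc_pr_curves(scores, labels)
  ref <- pROC::auc(pROC::roc(labels, scores, quiet = TRUE))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("stratified folds are disjoint, exhaustive and class-balanced", {
  labels <- rep(c(0L, 1L), c(60, 40))
  fold_id <- allerfuse:::stratified_folds(labels, 5L, seed = 2)
  expect_equal(sort(unique(fold_id)), 1:5)
  expect_equal(length(fold_id), 100L)
  for (f in 1:5) {
    expect_equal(sum(fold_id == f & labels == 0L), 12L)
    expect_equal(sum(fold_id == f & labels == 1L), 8L)
  }
  expect_error(allerfuse:::stratified_folds(rep(c(0L, 1L), c(3, 97)), 5L, 1),
               "at least 5")
})

test_that("cross-validation reports out-of-fold performance, not memorisation", {
  # random labels: the forest memorises training folds but cannot
  # generalise, so pooled accuracy must sit near chance, far from 1
  set.seed(67)
  rec <- random_records(60, len_range = c(30L, 60L), seed = 67,
                        labels = rep(c(0L, 1L), 30))
  cfg <- pipeline_config(encoders = "AAC", n_top = 20, q_components = 10,
                         n_trees = 50, seed = 67)
  cv <- suppressWarnings(cross_validate(rec, cfg))
  expect_equal(nrow(cv$scores), 60L)
  expect_setequal(cv$scores$id, rec$id)
  expect_lt(cv$acc, 0.8)
  expect_equal(length(cv$per_fold), 5L)
  expect_equal(sum(vapply(cv$per_fold, `[[`, numeric(1), "n")), 60)

  # but the fitted pipeline does memorise its own training data
  pipe <- suppressWarnings(train_pipeline(rec, cfg))
  expect_gt(mean(predict(pipe, rec)$call == rec$label), 0.95)
})

test_that("per-fold transforms are refit on the training fold only", {
  rec <- generate_records(synthetic_spec(n_per_class = 30, seed = 3,
                                         length_range = c(30L, 80L)))
  cfg <- pipeline_config(n_top = 50, q_components = 15, n_trees = 40,
                         seed = 3)
  cv <- suppressWarnings(cross_validate(rec, cfg))
  # evidence of per-fold refit: selected subsets differ across folds
  expect_equal(length(cv$fold_features), 5L)
  expect_gt(length(unique(cv$fold_features)), 1L)

  leaky <- cfg
  leaky$refit_per_fold <- FALSE
  cv2 <- suppressWarnings(cross_validate(rec, leaky))
  expect_equal(length(unique(cv2$fold_features)), 1L)
})

test_that("hold-out protocol splits 4:1 stratified and isolates validation labels", {
  rec <- generate_records(synthetic_spec(n_per_class = 50, seed = 5,
                                         length_range = c(30L, 80L)))
  cfg <- pipeline_config(n_top = 40, q_components = 10, n_trees = 40,
                         folds = 4, seed = 5)
  res <- suppressWarnings(holdout_protocol(rec, cfg))
  expect_equal(sum(res$split), 80L)
  train_labels <- rec$label[res$split]
  expect_equal(sum(train_labels), 40L)  # stratified
  expect_equal(res$validation$n, 20L)

  # same seed, same split and reports
  res2 <- suppressWarnings(holdout_protocol(rec, cfg))
  expect_identical(res$split, res2$split)
  expect_identical(serialize(res$validation, NULL),
                   serialize(res2$validation, NULL))

  # scrambling validation labels: training side and validation scores are
  # untouched; only the validation metric report changes
  valid_rec <- rec[!res$split, , drop = FALSE]
  scrambled <- valid_rec
  scrambled$label <- 1L - scrambled$label
  pred_orig <- predict(res$pipeline, valid_rec)
  pred_scram <- predict(res$pipeline, scrambled)
  expect_identical(pred_orig$score, pred_scram$score)
  rep_scram <- suppressWarnings(
    evaluate_scores(pred_scram$score, scrambled$label, cfg$threshold))
  expect_gt(res$validation$acc, 0.6)  # model carries real signal ...
  expect_equal(rep_scram$acc, 1 - res$validation$acc)  # ... so only the
  # held-out report moves, by exactly the label inversion
})

test_that("report tables round percentages to one decimal", {
  r <- evaluate_scores(c(0.9, 0.8, 0.3, 0.6), c(1L, 1L, 0L, 0L))
  tab <- report_table(validation = r)
  expect_equal(tab$dataset, "validation")
  expect_equal(tab$acc, 75.0)
  expect_equal(tab$sn, 100.0)
})
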