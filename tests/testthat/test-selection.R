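labelled_fm <- function(values, labels) {
  dimnames(values) <- list(sprintf("s%02d", seq_len(nrow(values))),
                           sprintf("f%02d", seq_len(ncol(values))))
  feature_matrix(values, labels = labels)
}

test_that("PCC ranking scores features by point-biserial correlation", {
  labels <- c(0L, 0L, 1L, 1L)
  values <- cbind(labels, 1 - labels, c(1, 2, 3, 4), rnorm(4))
  fm <- labelled_fm(values, labels)
  ranking <- rank_by_pcc(fm)
  expect_equal(ranking$feature_name[1:2], c("f01", "f02"))  # stable tie-break
  expect_equal(ranking$score[ranking$feature_name == "f01"], 1)
  expect_equal(ranking$score[ranking$feature_name == "f02"], -1)
  # hand-derived: cor(c(1,2,3,4), c(0,0,1,1)) = 2/sqrt(5) = 0.8944
  expect_equal(ranking$score[ranking$feature_name == "f03"],
               0.894427, tolerance = 1e-6)
  expect_equal(ranking$rank, 1:4)
})

test_that("ranking handles degenerate inputs", {
  labels <- rep(c(0L, 1L), 5)
  fm <- labelled_fm(cbind(rnorm(10), rep(2, 10)), labels)
  expect_warning(ranking <- rank_by_pcc(fm), "constant")
  expect_equal(ranking$score[ranking$feature_name == "f02"], 0)

  expect_error(rank_by_pcc(labelled_fm(matrix(rnorm(8), 4), rep(1L, 4))),
               "both classes")
  expect_error(rank_by_pcc(encode_aac(random_records(3, seed = 1))),
               "no labels")
})

test_that("ranking is invariant to affine rescaling of feature columns", {
  set.seed(9)
  labels <- rep(c(0L, 1L), each = 15)
  values <- matrix(rnorm(30 * 8), 30)
  values[, 1:3] <- values[, 1:3] + labels
  fm1 <- labelled_fm(values, labels)
  rescaled <- sweep(sweep(values, 2, c(5, -2, 0.1, 3, 1, 1, -7, 2), "*"),
                    2, rnorm(8), "+")
  fm2 <- labelled_fm(rescaled, labels)
  r1 <- rank_by_pcc(fm1)
  r2 <- rank_by_pcc(fm2)
  expect_identical(r1$feature_name, r2$feature_name)
  expect_equal(abs(r1$score), abs(r2$score))
})

test_that("select_top keeps ranking order and nests across n", {
  fm <- toy_labelled_fm(seed = 2)
  ranking <- rank_by_pcc(fm)
  expect_equal(select_top(ranking, fm, 1)$feature_names, "signal")
  all_cols <- select_top(ranking, fm, ncol(fm$values))
  expect_setequal(all_cols$feature_names, fm$feature_names)
  for (n1 in c(2L, 4L)) {
    expect_identical(select_top(ranking, fm, n1)$feature_names,
                     all_cols$feature_names[seq_len(n1)])
  }
  expect_error(select_top(ranking, fm, ncol(fm$values) + 1L), "between 1 and")
})

test_that("PCA fit matches an independent covariance eigendecomposition", {
  set.seed(31)
  values <- matrix(rnorm(300 * 50), 300)
  fm <- labelled_fm(values, rep(c(0L, 1L), 150))
  red <- fit_pca(fm, q = 10)
  eig <- eigen(stats::cov(values), symmetric = TRUE)
  expect_equal(red$explained_variance, eig$values[1:10], tolerance = 1e-6)
  # loadings orthonormal, variance non-increasing
  expect_equal(crossprod(red$loadings), diag(10), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_true(all(diff(red$explained_variance) <= 1e-12))
})

test_that("PCA is lossless at full rank and exact on low-rank data", {
  set.seed(17)
  values <- matrix(rnorm(40 * 6), 40)
  fm <- labelled_fm(values, rep(c(0L, 1L), 20))
  red <- fit_pca(fm, q = 6)
  scores <- apply_reducer(red, fm)
  reconstructed <- sweep(scores$values %*% t(red$loadings), 2,
                         red$center, "+")
  expect_equal(reconstructed, values, ignore_attr = TRUE, tolerance = 1e-8)

  planar <- matrix(rnorm(40 * 2), 40) %*% matrix(rnorm(2 * 6), 2)
  fm2 <- labelled_fm(planar, rep(c(0L, 1L), 20))
  red2 <- fit_pca(fm2, q = 2)
  total_var <- sum(apply(sweep(planar, 2, colMeans(planar)), 2, stats::var))
  expect_equal(sum(red2$explained_variance), total_var, tolerance = 1e-8)

  expect_error(fit_pca(fm, q = 7), "min\\(samples - 1, features\\)")
})

test_that("apply_reducer projects by (x - mean) %*% loadings and checks contracts", {
  set.seed(23)
  train <- labelled_fm(matrix(rnorm(60 * 8), 60), rep(c(0L, 1L), 30))
  red <- fit_pca(train, q = 3)

  held <- matrix(rnorm(5 * 8), 5,
                 dimnames = list(sprintf("h%d", 1:5), train$feature_names))
  got <- apply_reducer(red, feature_matrix(held))
  oracle <- sweep(held, 2, red$center) %*% red$loadings
  expect_equal(got$values, oracle, ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(colnames(got$values), paste0("PC", 1:3))

  mean_row <- matrix(red$center, 1, dimnames = list("m", train$feature_names))
  expect_equal(max(abs(apply_reducer(red, feature_matrix(mean_row))$values)),
               0, tolerance = 1e-10)

  # training score columns are uncorrelated with non-increasing variance
  scores <- apply_reducer(red, train)$values
  expect_equal(stats::cov(scores), diag(red$explained_variance),
               ignore_attr = TRUE, tolerance = 1e-6)

  wrong <- feature_matrix(held[, c(2:8, 1)])
  expect_error(apply_reducer(red, wrong), "feature contract")
})

test_that("IFS scan recovers that one informative feature suffices", {
  fm <- toy_labelled_fm(n_per_class = 25, p_noise = 8, seed = 13,
                        separation = 6)
  scan <- ifs_scan(fm, grid = c(1L, 9L), folds = 5L, seed = 13,
                   n_trees = 60L)
  expect_equal(scan$n_features, c(1L, 9L))
  expect_true(all(scan$accuracy > 0.9))
  expect_true(abs(scan$accuracy[1] - scan$accuracy[2]) < 0.1)
  expect_true(attr(scan, "best_n") %in% scan$n_features)

  # fully separated classes, full feature set: perfect accuracy
  sep <- toy_labelled_fm(n_per_class = 25, p_noise = 8, seed = 29,
                         separation = 10)
  full <- ifs_scan(sep, grid = 9L, folds = 5L, seed = 29, n_trees = 60L)
  expect_equal(full$accuracy, 1)
})
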