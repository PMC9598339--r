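test_that("PCA satisfies orthonormality, ordering and the eigen oracle", {
  set.seed(31)
  X <- matrix(rnorm(8 * 20), 8, 20)
  p <- fit_pca(X, 7)
  # orthonormal loadings
  expect_equal(p$loadings %*% t(p$loadings), diag(7), tolerance = 1e-8)
  # non-increasing variance shares summing to <= 1
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(p$explained_variance_ratio), 1 + 1e-12)
  # eigendecomposition oracle for the sample covariance
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(p$eigenvalues, ev[1:7], tolerance = 1e-8)
  # scores are the centered data projected on the loadings, zero-mean
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(p$scores, Xc %*% t(p$loadings), tolerance = 1e-10)
  expect_lt(max(abs(colMeans(p$scores))), 1e-10)
  # full reconstruction is lossless
  expect_equal(p$scores %*% p$loadings, Xc, tolerance = 1e-6)
})

test_that("a rank-1 set loads almost all variance on the first component", {
  set.seed(5)
  shape <- rnorm(30)
  X <- outer(rnorm(10, 1, 0.3), shape)
  p <- fit_pca(X, 3)
  expect_gt(p$explained_variance_ratio[1], 0.999)
})

test_that("variance_captured is cumulative, complete and bounded", {
  set.seed(8)
  X <- matrix(rnorm(12 * 9), 12, 9)
  p <- fit_pca(X, 9)
  expect_equal(variance_captured(p, 9), 1, tolerance = 1e-9)
  expect_identical(variance_captured(p, 0), 0)
  expect_equal(variance_captured(p, 3),
               sum(p$explained_variance_ratio[1:3]))
  expect_error(variance_captured(p, 10), "components")
  expect_error(fit_pca(X, 12), "n_components")
})

test_that("PLS fits a noiseless single-direction response exactly with 1 LV", {
  set.seed(41)
  # spectra vary along a single spectral direction; y follows it linearly
  t_ <- rnorm(25)
  direction <- rnorm(40)
  X <- 3 + outer(t_, direction)
  y1 <- 2 * t_ + 7
  m <- pls_fit(X, y1, 1)
  expect_lt(max(abs(pls_predict(m, X) - y1)), 1e-6 * stats::sd(y1))
})

test_that("full-rank PLS equals the least-squares solution", {
  set.seed(17)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(40)
  m <- pls_fit(X, y, 6)
  Xc <- sweep(X, 2, colMeans(X))
  b_ols <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  expect_lt(max(abs(m$regression_vector - b_ols)) / max(abs(b_ols)), 1e-6)
})

test_that("PLS agrees with an independent SIMPLS implementation", {
  set.seed(53)
  X <- matrix(rnorm(30 * 50), 30, 50)
  y <- drop(X[, 3] - 0.5 * X[, 20]) + rnorm(30, 0, 0.1)
  for (k in c(1, 3, 5)) {
    m <- pls_fit(X, y, k)
    o <- simpls_regression_vector(X, y, k)
    expect_lt(max(abs(m$regression_vector - o$b)) / max(abs(o$b)), 1e-6)
  }
})

test_that("PLS training is invariant to row permutation", {
  set.seed(61)
  X <- matrix(rnorm(20 * 15), 20, 15)
  y <- rnorm(20)
  m1 <- pls_fit(X, y, 4)
  perm <- sample(20)
  m2 <- pls_fit(X[perm, ], y[perm], 4)
  expect_equal(m1$regression_vector, m2$regression_vector, tolerance = 1e-10)
})

test_that("the affine form reproduces the sequential NIPALS prediction", {
  set.seed(71)
  X <- matrix(rnorm(18 * 25), 18, 25)
  y <- rnorm(18)
  m <- pls_fit(X, y, 5)
  x_new <- rnorm(25)
  # sequential: project on weights, deflate by loadings, accumulate q t
  resid <- x_new - m$x_mean
  yhat <- m$y_mean
  for (k in 1:5) {
    t_k <- sum(resid * m$weights[k, ])
    yhat <- yhat + m$y_loadings[k] * t_k
    resid <- resid - t_k * m$x_loadings[k, ]
  }
  expect_equal(pls_predict(m, matrix(x_new, 1)), yhat, tolerance = 1e-8)
  # centering identity: the training mean predicts y_mean
  expect_equal(pls_predict(m, matrix(colMeans(X), 1)), mean(y),
               tolerance = 1e-8)
})

test_that("PLS rejects degenerate targets and oversized models", {
  X <- matrix(rnorm(10 * 5), 10, 5)
  expect_error(pls_fit(X, rep(1, 10), 2), "degenerate target")
  expect_error(pls_fit(X, rnorm(10), 6), "parameter error")
  expect_error(plsda_fit(X, rep("CT", 10), 2), "degenerate target")
})

test_that("LOOCV matches a brute-force refit loop exactly", {
  set.seed(83)
  X <- matrix(rnorm(5 * 8), 5, 8)
  y <- rnorm(5)
  cv <- loocv_pls(X, y, max_lv = 2, cv_unit = "spectrum")
  for (k in 1:2) {
    expect_equal(cv$rmsecv_by_lv[k],
                 brute_force_loocv_rmse(X, y, k, seq_len(5)),
                 tolerance = 1e-10)
  }
})

test_that("LOOCV is near-perfect on a noiseless rank-1 problem", {
  set.seed(97)
  t_ <- rnorm(12)
  X <- outer(t_, rnorm(30))
  y <- 4 * t_ - 1
  cv <- loocv_pls(X, y, max_lv = 3, cv_unit = "spectrum")
  expect_lt(cv$rmsecv_by_lv[1], 1e-6 * stats::sd(y))
  expect_gt(cv$r_by_lv[1], 0.9999)
})

test_that("LOOCV on a null response stays at the no-information error", {
  mins <- vapply(1:20, function(i) {
    set.seed(1000 + i)
    X <- matrix(rnorm(40 * 20), 40, 20)
    y <- rnorm(40)
    cv <- loocv_pls(X, y, max_lv = 8, cv_unit = "spectrum")
    min(cv$rmsecv_by_lv) / stats::sd(y)
  }, numeric(1))
  expect_true(all(mins >= 0.8 & mins <= 1.3))
})

test_that("held-out predictions never see the held-out unit's response", {
  set.seed(113)
  X <- matrix(rnorm(9 * 12), 9, 12)
  y <- rnorm(9)
  cv1 <- loocv_pls(X, y, max_lv = 2, cv_unit = "spectrum")
  y2 <- y
  y2[4] <- y2[4] + 100 # corrupt one unit's response only
  cv2 <- loocv_pls(X, y2, max_lv = 2, cv_unit = "spectrum")
  # row 4's own prediction is unchanged (its y is not in its training fold)
  expect_equal(cv1$cv_predictions_by_lv[4, ], cv2$cv_predictions_by_lv[4, ],
               tolerance = 1e-10)
  # every other row's prediction changes (the corrupted y is in training)
  expect_true(all(abs(cv1$cv_predictions_by_lv[-4, 1] -
                        cv2$cv_predictions_by_lv[-4, 1]) > 1e-8))
})

test_that("sample-grouped folds hold replicates out together", {
  set.seed(127)
  ids <- rep(sprintf("s%d", 1:5), each = 3)
  X <- matrix(rnorm(15 * 10), 15, 10)
  y <- rep(rnorm(5), each = 3) + rnorm(15, 0, 0.01)
  cv <- loocv_pls(X, y, max_lv = 2, cv_unit = "sample", sample_ids = ids)
  # oracle: brute force over sample folds
  expect_equal(cv$rmsecv_by_lv[2],
               brute_force_loocv_rmse(X, y, 2, match(ids, unique(ids))),
               tolerance = 1e-10)
  expect_identical(cv$cv_unit, "sample")
})

test_that("latent-variable selection takes the first minimum", {
  expect_identical(select_latent_variables(c(5, 3, 3, 4)), 2L)
  expect_identical(select_latent_variables(rev(seq_len(8))), 8L)
  expect_identical(select_latent_variables(4.2), 1L)
})

test_that("PLS-DA separates well-separated classes and obeys the tie rule", {
  set.seed(131)
  n <- 20
  X <- rbind(matrix(rnorm(n * 10, 0), n, 10), matrix(rnorm(n * 10, 8), n, 10))
  labels <- rep(c("CT", "DMHBP"), each = n)
  m <- plsda_fit(X, labels, 2)
  expect_identical(plsda_classify(m, X), labels)
  # balanced classes: the training-mean spectrum scores exactly 1.5 -> DMHBP
  expect_identical(plsda_classify(m, matrix(colMeans(X), 1)), "DMHBP")
})

test_that("LDA separates distant Gaussians and matches the closed form", {
  set.seed(139)
  n <- 50
  train <- rbind(matrix(rnorm(n * 3, 0), n, 3), matrix(rnorm(n * 3, 10), n, 3))
  test <- rbind(matrix(rnorm(n * 3, 0), n, 3), matrix(rnorm(n * 3, 10), n, 3))
  labels <- rep(c("CT", "DMHBP"), each = n)
  m <- lda_fit(train, labels)
  expect_identical(lda_classify(m, test), labels)

  # two-feature closed form: with equal priors the boundary is
  # (x - (mu1+mu2)/2)' Sinv (mu2 - mu1) = 0
  mu1 <- m$class_means$CT
  mu2 <- m$class_means$DMHBP
  Sinv <- solve(m$pooled_covariance)
  a <- drop(Sinv %*% (mu2 - mu1))
  x0 <- (mu1 + mu2) / 2
  delta <- function(x) {
    s2 <- drop(x %*% (Sinv %*% mu2)) - drop(crossprod(mu2, Sinv %*% mu2)) / 2
    s1 <- drop(x %*% (Sinv %*% mu1)) - drop(crossprod(mu1, Sinv %*% mu1)) / 2
    (s2 - s1) + log(m$priors[2] / m$priors[1])
  }
  # at the midpoint the discriminant difference vanishes (equal priors)
  expect_equal(delta(matrix(x0, 1)), 0, tolerance = 1e-8)
  eps <- 1e-6 * a / sqrt(sum(a^2))
  expect_identical(lda_classify(m, matrix(x0 + eps, 1)), "DMHBP")
  expect_identical(lda_classify(m, matrix(x0 - eps, 1)), "CT")
})

test_that("LDA matches the reference implementation on seeded data", {
  skip_if_not_installed("MASS")
  set.seed(149)
  X <- rbind(matrix(rnorm(30 * 4, 0), 30, 4), matrix(rnorm(25 * 4, 1.2), 25, 4))
  labels <- c(rep("CT", 30), rep("DMHBP", 25))
  m <- lda_fit(X, labels)
  ref <- MASS::lda(X, grouping = labels)
  Xnew <- matrix(rnorm(40 * 4, 0.6), 40, 4)
  expect_identical(lda_classify(m, Xnew),
                   as.character(predict(ref, Xnew)$class))
})

test_that("LDA is at chance for identical class distributions", {
  set.seed(151)
  accs <- vapply(1:20, function(i) {
    train <- matrix(rnorm(200 * 3), 200, 3)
    labels <- rep(c("CT", "DMHBP"), each = 100)
    test <- matrix(rnorm(200 * 3), 200, 3)
    m <- lda_fit(train, labels)
    mean(lda_classify(m, test) == rep(c("CT", "DMHBP"), each = 100))
  }, numeric(1))
  expect_true(all(accs >= 0.4 & accs <= 0.6))
})

test_that("LDA requires at least two units per class", {
  X <- matrix(rnorm(10 * 2), 10, 2)
  expect_error(lda_fit(X, c(rep("CT", 9), "DMHBP")), "at least 2")
})
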