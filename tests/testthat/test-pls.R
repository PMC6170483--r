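test_that("a one-factor exact model is fitted exactly with one LV", {
  set.seed(1)
  n <- 15
  x1 <- rnorm(n)
  Xc <- cbind(x1, 0, 0, 0)
  Xc <- sweep(Xc, 2, colMeans(Xc))
  yc <- 2 * Xc[, 1]
  m <- fit_pls(Xc, yc, 1)
  expect_lt(rmse(yc, as.numeric(Xc %*% m$coef_b)), 1e-10)
})

test_that("full-rank PLS equals the least-squares solution", {
  set.seed(2)
  for (trial in 1:10) {
    n <- sample(12:30, 1); p <- sample(3:8, 1)
    Xc <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
    yc <- rnorm(n); yc <- yc - mean(yc)
    m <- fit_pls(Xc, yc, min(n - 1, p))
    b_ols <- ols_coef(Xc, yc)
    expect_lt(max(abs(m$coef_b - b_ols)) / max(abs(b_ols)), 1e-6)
  }
})

test_that("score-space and coefficient-space predictions agree", {
  set.seed(3)
  Xc <- scale(matrix(rnorm(60), 12, 5), scale = FALSE)
  yc <- rnorm(12); yc <- yc - mean(yc)
  m <- fit_pls(Xc, yc, 3)
  via_scores <- as.numeric(m$scores_T %*% m$y_loadings_q)
  via_coef <- as.numeric(Xc %*% m$coef_b)
  expect_equal(via_scores, via_coef, tolerance = 1e-8)
})

test_that("training RMSE is non-increasing in the LV count", {
  set.seed(4)
  Xc <- scale(matrix(rnorm(200), 20, 10), scale = FALSE)
  yc <- rnorm(20); yc <- yc - mean(yc)
  m <- fit_pls(Xc, yc, 9)
  errs <- apply(m$coef_path, 2, function(b) rmse(yc, as.numeric(Xc %*% b)))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("rank exhaustion stops early and reports achieved components", {
  Xc <- scale(cbind(rnorm(10), rnorm(10)), scale = FALSE)
  Xc <- cbind(Xc, Xc[, 1] + Xc[, 2])  # rank 2 in 3 columns
  yc <- Xc[, 1] - Xc[, 3]
  m <- fit_pls(Xc, yc, 3)
  expect_lte(m$n_lv, 2)
  expect_error(fit_pls(Xc, yc, 0), "n_lv")
  expect_error(fit_pls(Xc, yc, 10), "exceeds")
})

test_that("predict applies centering, matching hand arithmetic", {
  # 3 x 2 hand case
  X <- rbind(c(1, 2), c(3, 6), c(5, 4))
  y <- c(10, 30, 26)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  ct <- structure(list(x_means = xm, y_mean = ym),
                  class = "centering_transform")
  m <- fit_pls(Xc, yc, 2, centering = ct)
  expect_equal(predict(m, X),
               as.numeric(sweep(X, 2, xm) %*% m$coef_b) + ym,
               tolerance = 1e-12)
  # fitted values reproduce the calibration responses at full rank
  expect_equal(predict(m, X), y, tolerance = 1e-8)
  # the all-mean spectrum predicts the calibration response mean
  expect_equal(predict(m, matrix(xm, 1)), ym, tolerance = 1e-10)
  expect_error(predict(m, matrix(0, 1, 3)), "channels")
})

test_that("k-fold CV is seeded, exhaustive and parsimonious on ties", {
  ds <- toy_dataset(noise = 0)
  cv1 <- kfold_cv(ds$X, ds$y, k = 5, max_nlv = 6, seed = 9)
  cv2 <- kfold_cv(ds$X, ds$y, k = 5, max_nlv = 6, seed = 9)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(cv1$rmsecv_by_nlv, cv2$rmsecv_by_nlv)
  # every sample predicted exactly once out-of-fold
  expect_equal(sort(unique(cv1$fold_assignment)), 1:5)
  expect_length(cv1$cv_predictions, nrow(ds$X))
})

test_that("perfectly linear rank-one data select one LV by parsimony", {
  set.seed(10)
  t <- rnorm(20)
  X <- outer(t, c(1, 2, 3, 4))
  y <- 10 + 5 * t
  cv <- kfold_cv(X, y, k = 5, max_nlv = 3, seed = 1)
  # one component fits exactly; further candidates tie and the lowest
  # count wins
  expect_equal(cv$chosen_nlv, 1L)
  expect_lt(cv$rmsecv_by_nlv[1], 1e-8)
})

test_that("CV out-of-fold error matches a duplicated-data construction", {
  # each sample twice; folds separate the copies, so the out-of-fold
  # prediction of a copy comes from a model trained on identical data:
  # RMSECV at A equals the training RMSE of that model
  set.seed(6)
  n <- 10; p <- 4
  X1 <- matrix(rnorm(n * p), n, p)
  y1 <- rnorm(n)
  X <- rbind(X1, X1); y <- c(y1, y1)
  foldid <- rep(1:2, each = n)
  cv <- kfold_cv(X, y, foldid = foldid, max_nlv = 3)
  Xc <- scale(X1, scale = FALSE); yc <- y1 - mean(y1)
  for (a in 1:3) {
    m <- fit_pls(Xc, yc, a)
    expect_equal(cv$rmsecv_by_nlv[a],
                 rmse(yc, as.numeric(Xc %*% m$coef_b)), tolerance = 1e-10)
  }
})

test_that("metric formulas reproduce hand computations", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 6)), sqrt(3), tolerance = 1e-12)
  expect_equal(q2(c(1, 2, 3), c(1, 2, 6)), -3.5, tolerance = 1e-12)
  expect_equal(sd_over_runs(c(1, 2, 3)), 1, tolerance = 1e-12)
  y <- c(4, 7, 1, 9)
  expect_equal(rmse(y, y), 0)
  expect_equal(q2(y, y), 1)
  expect_equal(q2(y, rep(mean(y), 4)), 0)
  expect_equal(sd_over_runs(rep(3, 5)), 0)
  expect_error(q2(c(1, 1), c(1, 2)), "constant")
  expect_error(sd_over_runs(1), "at least 2")
  expect_error(rmse(1:3, 1:2), "length")
})

test_that("q2 and rmse satisfy their algebraic identity and scaling", {
  set.seed(7)
  for (trial in 1:10) {
    y <- rnorm(12); yhat <- rnorm(12)
    expect_equal(q2(y, yhat),
                 1 - (12 * rmse(y, yhat)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
    s <- runif(1, 0.1, 10)
    expect_equal(rmse(s * y, s * yhat), s * rmse(y, yhat),
                 tolerance = 1e-12)
    expect_equal(q2(s * y, s * yhat), q2(y, yhat), tolerance = 1e-12)
  }
})
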