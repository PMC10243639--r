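test_that("lagged design has the documented shift structure", {
  x <- matrix(0, 10, 1)
  x[4, 1] <- 1
  D <- build_lagged_design(x, 0:2)
  expect_equal(which(D[, 1] == 1), 4L)   # lag 0
  expect_equal(which(D[, 2] == 1), 5L)   # lag 1: feature from t-1
  expect_equal(which(D[, 3] == 1), 6L)
  # lag 0 only reproduces the features
  m <- matrix(rnorm(20), 10, 2)
  expect_equal(unname(build_lagged_design(m, 0L)), m)
  # negative lag anticipates by one frame
  Dn <- build_lagged_design(x, -1L)
  expect_equal(which(Dn[, 1] == 1), 3L)
  expect_error(build_lagged_design(matrix(0, 5, 0), 0:1), "empty")
})

test_that("banded ridge equals the penalized normal-equation oracle", {
  for (seed in 1:4) {
    prob <- random_ridge_problem(n = 60, p_groups = c(3, 5, 2), seed = seed)
    w <- fit_banded_ridge(prob$X, prob$Y, prob$lam_col)
    expect_equal(unname(w), unname(ridge_oracle(prob$X, prob$Y, prob$lam_col)),
                 tolerance = 1e-8)
  }
  # orthonormal design, lambda -> 0: weights equal X'y
  q <- qr.Q(qr(matrix(rnorm(320), 40, 8)))
  y <- rnorm(40)
  expect_equal(drop(fit_banded_ridge(q, y, 1e-12)), drop(crossprod(q, y)),
               tolerance = 1e-6)
  expect_error(fit_banded_ridge(matrix(c(1, NA), 1, 2), 1, 1), "finite")
})

test_that("an extreme group lambda shrinks that group toward exclusion", {
  set.seed(8)
  X <- matrix(rnorm(200 * 6), 200, 6)
  beta <- c(1, -2, 1.5, 0.5, -1, 2)
  y <- X %*% beta + rnorm(200, 0, 0.1)
  lam <- c(rep(1, 3), rep(1e10, 3))
  w <- fit_banded_ridge(X, y, lam)
  expect_lt(max(abs(w[4:6, ])), 1e-5)
  w_reduced <- fit_banded_ridge(X[, 1:3], y, rep(1, 3))
  expect_equal(w[1:3, ], w_reduced[, 1], tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("cross-validation recovers noiseless responses and nulls out noise", {
  set.seed(9)
  feats <- matrix(rnorm(2000 * 3), 2000, 3)
  bank <- regressor_bank(list(a = feats), frame_rate_hz = 100)
  lags <- lag_frames(c(0, 100), 100)
  truth <- rnorm(3 * length(lags))
  D <- build_lagged_design(scale_columns(feats)$x, lags)
  y <- D %*% truth
  cv <- crossval_predict(bank, y, c(a = 1e-4), lags_ms = c(0, 100),
                         n_folds = 5)
  expect_true(all(tanh(cv$mean_z) > 0.99))
  # independent response: mean z near zero
  cv0 <- crossval_predict(bank, rnorm(2000), c(a = 1), lags_ms = c(0, 100))
  expect_lt(abs(mean(cv0$mean_z)), 3 / sqrt(2000))
  # the Fisher transform itself
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-6)
})

test_that("cross-validated z is invariant to electrode-wise affine transforms", {
  set.seed(10)
  feats <- matrix(rnorm(1500 * 2), 1500, 2)
  bank <- regressor_bank(list(a = feats), frame_rate_hz = 100)
  D <- build_lagged_design(scale_columns(feats)$x, lag_frames(c(0, 100), 100))
  y <- D %*% rnorm(2 * 11) + rnorm(1500)
  cv1 <- crossval_predict(bank, y, c(a = 1), lags_ms = c(0, 100))
  cv2 <- crossval_predict(bank, 5 * y - 3, c(a = 1), lags_ms = c(0, 100))
  expect_equal(cv1$z, cv2$z, tolerance = 1e-10)
})

test_that("sequential tuning favors informative groups and is deterministic", {
  set.seed(12)
  n <- 1500
  informative <- matrix(rnorm(n * 2), n, 2)
  noisy <- matrix(rnorm(n * 2), n, 2)
  lags <- lag_frames(c(0, 50), 100)
  D <- build_lagged_design(scale_columns(informative)$x, lags)
  y <- D %*% rnorm(ncol(D)) + rnorm(n, 0, 1)
  bank <- regressor_bank(list(inf = informative, noise = noisy), 100)
  lam <- suppressWarnings(
    tune_lambdas_sequential(bank, y, lags_ms = c(0, 50), n_folds = 3,
                            n_angles = 9, radii = 10^seq(-1, 4),
                            grid = 10^seq(-1, 4)))
  expect_lt(lam["inf"], lam["noise"])
  lam2 <- suppressWarnings(
    tune_lambdas_sequential(bank, y, lags_ms = c(0, 50), n_folds = 3,
                            n_angles = 9, radii = 10^seq(-1, 4),
                            grid = 10^seq(-1, 4)))
  expect_equal(lam, lam2)
})

test_that("the model object carries weights, methods, and group bookkeeping", {
  set.seed(13)
  feats <- list(a = matrix(rnorm(800 * 2), 800, 2),
                b = matrix(rnorm(800 * 3), 800, 3))
  bank <- regressor_bank(feats, 100)
  y <- matrix(rnorm(800 * 2), 800, 2)
  fit <- trf(bank, y, lambdas = c(a = 1, b = 10), lags_ms = c(0, 100),
             n_folds = 3)
  expect_s3_class(fit, "trf")
  expect_equal(dim(fit$weights), c(11L, 5L, 2L))
  expect_identical(dim(coef(fit)), dim(fit$weights))
  expect_output(print(fit), "trf")
  s <- summary(fit)
  expect_named(s$group_power, c("a", "b"))
  pred <- predict(fit, bank)
  expect_equal(dim(pred), c(800L, 2L))
  # prediction correlates with the training response as well as the
  # full-data fit allows (sanity, not a statistical claim)
  expect_true(is.finite(cor(pred[, 1], y[, 1])))
})

test_that("reference lambdas cover the eight standard groups verbatim", {
  lam <- lambda_defaults()
  expect_identical(names(lam),
                   c("spectrogram", "glimpsed_edges", "masked_edges",
                     "glimpsed_phoneme_onsets", "masked_phoneme_onsets",
                     "glimpsed_phonetic", "masked_phonetic", "word_onsets"))
  expect_identical(unname(lam), c(42.7, 13.5, 10.0, 31.6, 17.8, 144, 215, 31.6))
})
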