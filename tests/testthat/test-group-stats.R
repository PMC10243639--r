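test_that("hierarchical bootstrap p-values behave at the extremes", {
  subj <- rep(1:4, each = 5)
  hb <- hierarchical_bootstrap(rep(1, 20), subj, n_boot = 2000, seed = 1)
  expect_equal(hb$p, 1 / 2000)   # floored, never 0
  # symmetric values across subjects: p near 0.5
  set.seed(2)
  vals <- rnorm(40)
  vals <- vals - mean(vals)
  hb2 <- hierarchical_bootstrap(vals, rep(1:8, each = 5), n_boot = 4000,
                                seed = 3)
  expect_gt(hb2$p, 0.2)
  expect_lt(hb2$p, 0.8)
  # p(greater) + p(less) ~ 1 up to ties
  g <- hierarchical_bootstrap(vals, rep(1:8, each = 5), n_boot = 4000,
                              seed = 5, side = "greater")
  l <- hierarchical_bootstrap(vals, rep(1:8, each = 5), n_boot = 4000,
                              seed = 5, side = "less")
  expect_equal(g$p + l$p, 1, tolerance = 0.02)
  expect_error(hierarchical_bootstrap(1, "a", n_boot = 1000), "two electrodes")
  # reproducible and respects the fast path == generic path for the mean
  f1 <- hierarchical_bootstrap(vals, rep(1:8, each = 5), n_boot = 500,
                               seed = 7)
  f2 <- hierarchical_bootstrap(vals, rep(1:8, each = 5), n_boot = 500,
                               seed = 7)
  expect_identical(f1$distribution, f2$distribution)
})

test_that("fast and generic bootstrap paths agree in distribution", {
  set.seed(8)
  vals <- rnorm(30, 0.3)
  subj <- rep(1:6, each = 5)
  fast <- hierarchical_bootstrap(vals, subj, n_boot = 4000, seed = 11)
  gen <- hierarchical_bootstrap(vals, subj, statistic = mean, n_boot = 4000,
                                seed = 11)
  # same resampling scheme, different stream consumption: compare moments
  expect_lt(abs(mean(fast$distribution) - mean(gen$distribution)), 0.03)
  expect_lt(abs(sd(fast$distribution) - sd(gen$distribution)), 0.03)
})

test_that("TRF power time course is a sign-invariant squared average", {
  set.seed(14)
  feats <- list(a = matrix(rnorm(600 * 2), 600, 2))
  bank <- regressor_bank(feats, 100)
  fit <- trf(bank, matrix(rnorm(600 * 3), 600, 3), lambdas = c(a = 1),
             lags_ms = c(0, 200), n_folds = 2, cv = FALSE)
  # hand-crafted weights: delta at 150 ms for every electrode
  fit$weights[] <- 0
  i150 <- which(fit$lag_ms == 150)
  fit$weights[i150, , ] <- 2
  pw <- trf_power_timecourse(fit)
  expect_equal(pw$mean[i150], 4)
  expect_equal(sum(pw$mean[-i150]), 0)
  expect_equal(which.max(pw$mean), i150)
  # sign flip leaves power unchanged
  fit2 <- fit
  fit2$weights <- -fit2$weights
  expect_equal(trf_power_timecourse(fit2)$mean, pw$mean)
  # zero weights give a zero curve
  fit$weights[] <- 0
  expect_equal(sum(trf_power_timecourse(fit)$mean), 0)
  expect_error(trf_power_timecourse(fit, electrodes = integer(0)), "empty")
})

test_that("encoding latency finds peaks at 5 ms resolution", {
  lag_ms <- seq(0, 500, by = 10)
  # a Gaussian bump centered off-grid at 190 ms is recovered within 10 ms
  curve <- exp(-(lag_ms - 190)^2 / (2 * 40^2))
  expect_lt(abs(encoding_latency(curve, lag_ms) - 190), 10)
  # an on-grid peak is unchanged by upsampling
  delta <- numeric(length(lag_ms)); delta[16] <- 1
  expect_equal(encoding_latency(delta, lag_ms), lag_ms[16])
  # two equal adjacent samples from a symmetric bump land between them
  sym <- exp(-(lag_ms - 155)^2 / (2 * 30^2))
  expect_equal(encoding_latency(sym, lag_ms), 155)
  # flat curve: undefined
  expect_true(is.na(encoding_latency(rep(1, 51), lag_ms)))
  # ties break to the earliest peak
  two <- numeric(51); two[c(11, 31)] <- 1
  expect_equal(encoding_latency(two, lag_ms), lag_ms[11])
})

test_that("time-course significance flags encoded windows and not nulls", {
  set.seed(15)
  n_el <- 20; n_lag <- 26
  subj <- rep(1:4, each = 5)
  shuf <- array(abs(rnorm(n_el * n_lag * 5, 1, 0.2)), c(n_el, n_lag, 5))
  # null: true == mean shuffled -> few/no flags
  true_null <- apply(shuf, c(1, 2), mean)
  res <- timecourse_significance(true_null, shuf, subj, n_boot = 500, seed = 2)
  expect_lt(mean(res$significant), 0.15)
  # encoded bump at lags 10:14 -> contiguous flagged window there
  true_enc <- true_null
  true_enc[, 10:14] <- true_enc[, 10:14] + 2
  res2 <- timecourse_significance(true_enc, shuf, subj, n_boot = 500, seed = 2)
  expect_true(all(res2$significant[10:14]))
  # all-zero everywhere: nothing flagged
  res3 <- timecourse_significance(matrix(0, n_el, n_lag),
                                  array(0, c(n_el, n_lag, 5)), subj,
                                  n_boot = 500, seed = 2)
  expect_false(any(res3$significant))
})

test_that("latency comparison reports rank-sum, paired t, and bootstrap", {
  subj <- rep(1:7, length.out = 62)
  # identical sets: two-sided rank-sum p near 1
  same <- rnorm(62, 200, 30)
  res <- latency_comparison(same, same, subjects = subj, n_boot = 2000,
                            seed = 1)
  expect_gt(res$ranksum_p, 0.9)
  # constructed exact offset: mean difference 95, vanishing p
  gl <- rnorm(62, 150, 30)
  res2 <- latency_comparison(gl, gl + 95, subjects = subj, n_boot = 2000,
                             seed = 2)
  expect_equal(res2$mean_difference_ms, 95)
  expect_lt(res2$ranksum_p, 0.001)
  expect_lt(res2$boot_p, 0.001)
  # jittered offset recovered within 15 ms
  set.seed(16)
  d <- 50 + rnorm(62, 0, 40)
  res3 <- latency_comparison(gl, gl + d, subjects = subj, n_boot = 2000,
                             seed = 3)
  expect_lt(abs(res3$mean_difference_ms - 50), 15)
  # too few electrodes: missing statistics
  res4 <- latency_comparison(c(1, 2), c(2, 3))
  expect_true(is.na(res4$ranksum_p))
  expect_true(is.na(res4$t))
})

test_that("anatomical correlation tracks monotone gradients", {
  subj <- rep(1:5, each = 4)
  coord <- seq_len(20)
  dz <- rev(seq_len(20)) / 20
  res <- anatomical_correlation(dz, coord, subj, n_boot = 1000, seed = 1)
  expect_equal(res$rho, -1)
  expect_lt(res$p, 0.01)
  # rank invariance under monotone coordinate transforms
  res2 <- anatomical_correlation(dz, exp(coord / 3), subj, n_boot = 1000,
                                 seed = 1)
  expect_equal(res2$rho, res$rho)
  expect_error(anatomical_correlation(dz, rep(1, 20), subj), "constant")
  expect_error(anatomical_correlation(dz[1:4], coord[1:4], subj[1:4]),
               "at least 5")
})
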