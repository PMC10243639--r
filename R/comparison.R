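# Feature-encoding quantification: baseline-vs-null ablation, shuffled-
# feature electrode tests, the glimpse SNR-threshold sweep, and joint
# glimpsed/masked encoding classification.

#' Feature ablation test (baseline vs null model)
#'
#' Refits the encoding model with one feature group removed, using identical
#' frozen lambdas, folds, and lag axis, and measures each electrode's drop
#' in cross-validated Fisher-z prediction accuracy (`delta_z = baseline z -
#' null z`). Population-level significance combines a one-sided paired t
#' test across electrodes with a hierarchical bootstrap of the mean
#' improvement (the headline p, robust to subject nesting).
#'
#' @param bank a [regressor_bank()] with frozen lambdas (or pass `lambdas`).
#' @param response time x electrodes matrix.
#' @param drop_group name of the group to ablate.
#' @param subjects subject tag per electrode.
#' @param lambdas optional named per-group penalties.
#' @param lags_ms,n_folds model settings as in [crossval_predict()].
#' @param n_boot bootstrap iterates (default 10000).
#' @param seed integer seed for the bootstrap.
#' @param baseline_cv optionally, a precomputed [crossval_predict()] result
#'   for the baseline bank (reused across several ablations).
#' @return object of class `ablation_result`: data frame of per-electrode
#'   `delta_z` with subject tags, plus `t`, `t_p`, `boot_p`, and the two CV
#'   objects.
#' @export
ablation_test <- function(bank, response, drop_group, subjects,
                          lambdas = NULL, lags_ms = c(0, 500), n_folds = 5,
                          n_boot = 10000, seed = NULL, baseline_cv = NULL) {
  if (!drop_group %in% names(bank$groups)) {
    stop("cannot ablate a group absent from the baseline model: ", drop_group)
  }
  lam <- resolve_lambdas(bank, lambdas)
  base <- baseline_cv %||%
    crossval_predict(bank, response, lam, lags_ms, n_folds)
  nullm <- crossval_predict(bank_drop(bank, drop_group), response,
                            lam[setdiff(names(lam), drop_group)],
                            lags_ms, n_folds)
  delta_z <- base$mean_z - nullm$mean_z
  stopifnot(length(subjects) == length(delta_z))
  tt <- stats::t.test(delta_z, alternative = "greater")
  hb <- hierarchical_bootstrap(delta_z, subjects, n_boot = n_boot,
                               seed = seed, side = "greater")
  structure(
    list(feature = drop_group,
         table = data.frame(subject = subjects, delta_z = delta_z),
         t = unname(tt$statistic), t_p = tt$p.value, boot_p = hb$p,
         mean_delta_z = mean(delta_z), baseline = base, null = nullm),
    class = "ablation_result"
  )
}

#' @export
print.ablation_result <- function(x, ...) {
  cat(sprintf(
    "<ablation> %s: mean delta z = %.4f over %d electrodes; t = %.2f (p = %.3g), bootstrap p = %.3g\n",
    x$feature, x$mean_delta_z, nrow(x$table), x$t, x$t_p, x$boot_p))
  invisible(x)
}

#' Per-electrode significance against shuffled-feature models
#'
#' Replaces one group with shuffled versions of itself (the group's own
#' shuffling scheme: local time shuffle for acoustic features, mapping
#' shuffle for phonetics, random-phoneme onsets for words), refits the model
#' `n_shuffles` times, and tests per electrode whether the baseline
#' prediction accuracy exceeds the shuffled distribution (one-sided,
#' one-sample t test on baseline minus shuffled z). Used to select
#' electrodes for latency and anatomy analyses.
#'
#' @inheritParams ablation_test
#' @param group name of the group to shuffle; the bank must carry a
#'   shuffler for it.
#' @param n_shuffles number of shuffled models (default 10).
#' @param alpha per-electrode significance level (default 0.05, uncorrected).
#' @return object of class `shuffle_test`: per-electrode data frame with
#'   `baseline_z`, `shuffled_mean_z`, `p`, `significant`.
#' @export
shuffled_feature_test <- function(bank, response, group, lambdas = NULL,
                                  lags_ms = c(0, 500), n_folds = 5,
                                  n_shuffles = 10, alpha = 0.05, seed = 1,
                                  baseline_cv = NULL) {
  shuffler <- bank$shufflers[[group]]
  if (is.null(shuffler)) {
    stop("group has no shuffling scheme defined: ", group)
  }
  lam <- resolve_lambdas(bank, lambdas)
  base <- baseline_cv %||%
    crossval_predict(bank, response, lam, lags_ms, n_folds)
  shuf_z <- vapply(seq_len(n_shuffles), function(s) {
    shuffled <- bank_replace(bank, group, shuffler(seed + s))
    crossval_predict(shuffled, response, lam, lags_ms, n_folds)$mean_z
  }, numeric(length(base$mean_z)))            # electrodes x n_shuffles
  p <- vapply(seq_len(nrow(shuf_z)), function(e) {
    d <- base$mean_z[e] - shuf_z[e, ]
    if (stats::sd(d) < .Machine$double.eps) {
      return(if (mean(d) > 0) 0 else 1)
    }
    stats::t.test(d, alternative = "greater")$p.value
  }, numeric(1))
  structure(
    list(group = group,
         table = data.frame(baseline_z = base$mean_z,
                            shuffled_mean_z = rowMeans(shuf_z),
                            p = p, significant = p < alpha),
         alpha = alpha, n_shuffles = n_shuffles),
    class = "shuffle_test"
  )
}

#' @export
print.shuffle_test <- function(x, ...) {
  cat(sprintf("<shuffle test> %s: %d / %d electrodes significant at alpha = %g (%d shuffles)\n",
              x$group, sum(x$table$significant), nrow(x$table), x$alpha,
              x$n_shuffles))
  invisible(x)
}

#' Glimpse SNR-threshold sweep
#'
#' Rebuilds the glimpsed/masked phoneme regressors at each candidate SNR
#' threshold, refits the model with frozen lambdas, and records the mean
#' cross-validated Fisher z over electrodes. Reports the optimal threshold
#' and, for every other threshold, a hierarchical-bootstrap comparison of
#' its per-electrode accuracies against the optimum.
#'
#' @param bank_builder function `function(threshold_db)` returning the
#'   [regressor_bank()] for that threshold (lambdas must be frozen; they are
#'   conventionally estimated once at 0 dB).
#' @param thresholds_db sorted numeric vector of thresholds to evaluate.
#' @param response time x electrodes matrix.
#' @param subjects subject tag per electrode.
#' @param lags_ms,n_folds model settings.
#' @param n_boot bootstrap iterates for the per-threshold comparisons.
#' @param seed integer seed.
#' @return object of class `snr_sweep`: data frame `curve` with `threshold_db`,
#'   `mean_z`, `boot_p_vs_best`; plus `best_db`.
#' @export
snr_threshold_sweep <- function(bank_builder, thresholds_db, response,
                                subjects, lags_ms = c(0, 500), n_folds = 5,
                                n_boot = 1000, seed = NULL) {
  if (length(thresholds_db) == 0L) stop("empty threshold list")
  stopifnot(!is.unsorted(thresholds_db))
  zmat <- vapply(thresholds_db, function(th) {
    bank <- bank_builder(th)
    crossval_predict(bank, response, NULL, lags_ms, n_folds)$mean_z
  }, numeric(ncol(as.matrix(response))))      # electrodes x thresholds
  mean_z <- colMeans(zmat, na.rm = TRUE)
  best <- which.max(mean_z)
  boot_p <- vapply(seq_along(thresholds_db), function(i) {
    if (i == best) return(NA_real_)
    hierarchical_bootstrap(zmat[, best] - zmat[, i], subjects,
                           n_boot = n_boot,
                           seed = if (is.null(seed)) NULL else seed + i,
                           side = "greater")$p
  }, numeric(1))
  structure(
    list(curve = data.frame(threshold_db = thresholds_db, mean_z = mean_z,
                            boot_p_vs_best = boot_p),
         best_db = thresholds_db[best], z_by_electrode = zmat),
    class = "snr_sweep"
  )
}

#' Batch SNR-threshold sweep over several response sets
#'
#' Evaluates the mean cross-validated Fisher z per threshold for many
#' response matrices that share one stimulus (e.g., repeated ground-truth
#' draws from [simulate_responses()]). Per threshold and fold, the design,
#' its Gram matrix, and its Cholesky factor are computed once and reused
#' for every response set, so a calibration study over dozens of runs costs
#' little more than a single sweep. The per-run numbers are identical to
#' running [snr_threshold_sweep()] on each response set separately.
#'
#' @param bank_builder function `function(threshold_db)` returning the
#'   [regressor_bank()] for that threshold, with frozen lambdas.
#' @param thresholds_db sorted numeric thresholds.
#' @param responses_list list of time x electrodes response matrices.
#' @param lags_ms,n_folds model settings.
#' @return list with `mean_z` (runs x thresholds matrix) and `best_db`
#'   (argmax per run).
#' @export
snr_threshold_sweep_batch <- function(bank_builder, thresholds_db,
                                      responses_list, lags_ms = c(0, 500),
                                      n_folds = 5) {
  if (length(thresholds_db) == 0L) stop("empty threshold list")
  stopifnot(!is.unsorted(thresholds_db), length(responses_list) >= 1L)
  n_runs <- length(responses_list)
  mean_z <- matrix(NA_real_, n_runs, length(thresholds_db))
  for (ti in seq_along(thresholds_db)) {
    bank <- bank_builder(thresholds_db[ti])
    lam <- resolve_lambdas(bank, NULL)
    lags <- lag_frames(lags_ms, bank$frame_rate_hz)
    X <- do.call(cbind, bank$groups)
    group_sizes <- vapply(bank$groups, ncol, integer(1))
    lam_col <- rep(lam[rep(seq_along(bank$groups), group_sizes)],
                   each = length(lags))
    nt <- nrow(X)
    ids <- fold_ids(nt, n_folds)
    span_lo <- max(0L, max(lags))
    span_hi <- max(0L, -min(lags))
    z_acc <- matrix(0, n_runs, ncol(responses_list[[1]]))
    n_acc <- matrix(0L, n_runs, ncol(responses_list[[1]]))
    for (k in seq_len(n_folds)) {
      train <- which(ids != k)
      test <- which(ids == k)
      sc <- scale_columns(X[train, , drop = FALSE])
      D <- build_lagged_design(scale_columns(X, sc$center, sc$scale)$x, lags)
      score <- test[test >= min(test) + span_lo & test <= max(test) - span_hi]
      A <- crossprod(D[train, , drop = FALSE])
      diag(A) <- diag(A) + lam_col
      ch <- chol(A)
      Dtr <- D[train, , drop = FALSE]
      Dte <- D[score, , drop = FALSE]
      rm(D)
      for (r in seq_len(n_runs)) {
        Y <- as.matrix(responses_list[[r]])
        yc <- colMeans(Y[train, , drop = FALSE])
        b <- crossprod(Dtr, sweep(Y[train, , drop = FALSE], 2L, yc, "-"))
        w <- backsolve(ch, forwardsolve(t(ch), b))
        zk <- fold_z(list(Xtest = Dte, Ytest = Y[score, , drop = FALSE]), w)
        ok <- !is.na(zk)
        z_acc[r, ok] <- z_acc[r, ok] + zk[ok]
        n_acc[r, ok] <- n_acc[r, ok] + 1L
      }
    }
    mean_z[, ti] <- rowMeans(z_acc / pmax(n_acc, 1L))
  }
  list(mean_z = mean_z,
       best_db = thresholds_db[apply(mean_z, 1L, which.max)])
}

#' @export
print.snr_sweep <- function(x, ...) {
  cat(sprintf("<snr sweep> optimal glimpse SNR threshold: %g dB\n", x$best_db))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Classify joint glimpsed/masked encoding per electrode
#'
#' Four-way partition of electrodes by whether they significantly encode
#' glimpsed features, masked features, both, or neither.
#'
#' @param sig_glimpsed,sig_masked logical vectors from per-electrode
#'   significance tests (e.g., [shuffled_feature_test()]).
#' @param region optional region label per electrode for the count table.
#' @return list with `category` (factor per electrode with levels `none`,
#'   `glimpsed-only`, `masked-only`, `both`) and `counts` (by region when
#'   given).
#' @export
classify_joint_encoding <- function(sig_glimpsed, sig_masked, region = NULL) {
  stopifnot(length(sig_glimpsed) == length(sig_masked))
  cat_ <- ifelse(sig_glimpsed & sig_masked, "both",
          ifelse(sig_glimpsed, "glimpsed-only",
          ifelse(sig_masked, "masked-only", "none")))
  category <- factor(cat_, levels = c("none", "glimpsed-only", "masked-only",
                                      "both"))
  counts <- if (is.null(region)) table(category)
            else table(region = region, category = category)
  list(category = category, counts = counts)
}
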