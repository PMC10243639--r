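# Population inference that respects the nesting of electrodes within
# subjects: hierarchical bootstrap p-values, TRF power time courses and
# latencies, latency contrasts, and anatomical-gradient correlations.

#' Hierarchical bootstrap
#'
#' Resamples subjects with replacement, then electrodes within each sampled
#' subject with replacement (keeping that subject's own electrode count), and
#' recomputes the statistic on every iterate. This respects the
#' non-independence of electrodes recorded from the same subject. The
#' one-sided p-value is the fraction of iterates on the null side of
#' `null_value`; it is floored at `1 / n_boot` (never reported as 0).
#'
#' @param values numeric vector (one value per electrode) or a data frame /
#'   matrix with one row per electrode for multivariate statistics.
#' @param subjects subject tag per electrode.
#' @param statistic function of the resampled values (vector or data subset)
#'   returning a scalar; default is the pooled mean.
#' @param n_boot number of bootstrap iterates (default 10000).
#' @param seed integer seed.
#' @param side `"greater"` (H1: statistic > null), `"less"`, or
#'   `"two.sided"`.
#' @param null_value null comparison point (default 0).
#' @return list of class `hboot` with `p`, `estimate` (statistic on the
#'   original sample), `distribution`, `n_boot`, `side`.
#' @export
hierarchical_bootstrap <- function(values, subjects, statistic = NULL,
                                   n_boot = 10000, seed = NULL,
                                   side = c("greater", "less", "two.sided"),
                                   null_value = 0) {
  side <- match.arg(side)
  multiv <- is.data.frame(values) || is.matrix(values)
  if (multiv && is.null(statistic)) {
    stop("a statistic function is required for multivariate values")
  }
  n <- if (multiv) nrow(values) else length(values)
  stopifnot(length(subjects) == n)
  if (n < 2L) stop("need at least two electrodes for the bootstrap")
  idx_by_subj <- split(seq_len(n), subjects)
  ns <- length(idx_by_subj)
  sizes <- lengths(idx_by_subj)

  dist <- with_seed(seed, {
    if (is.null(statistic) && !multiv && length(unique(sizes)) == 1L) {
      # fast path: pooled mean with equal electrode counts, fully vectorized
      ne <- sizes[1L]
      vm <- matrix(values[unlist(idx_by_subj)], nrow = ne)   # electrodes x subj
      subj_draw <- matrix(sample.int(ns, n_boot * ns, replace = TRUE),
                          n_boot, ns)
      el_draw <- matrix(sample.int(ne, n_boot * ns * ne, replace = TRUE),
                        n_boot * ns, ne)
      picked <- matrix(vm[cbind(as.vector(el_draw),
                                rep(as.vector(subj_draw), ne))],
                       n_boot * ns, ne)
      rowMeans(matrix(rowMeans(picked), n_boot, ns))
    } else {
      stat <- statistic %||% mean
      vapply(seq_len(n_boot), function(b) {
        subj <- sample.int(ns, ns, replace = TRUE)
        rows <- unlist(lapply(subj, function(s) {
          ix <- idx_by_subj[[s]]
          ix[sample.int(length(ix), length(ix), replace = TRUE)]
        }), use.names = FALSE)
        if (multiv) stat(values[rows, , drop = FALSE]) else stat(values[rows])
      }, numeric(1))
    }
  })
  est <- if (is.null(statistic)) mean(values) else statistic(values)
  p_lo <- mean(dist <= null_value)   # evidence against "greater"
  p_hi <- mean(dist >= null_value)
  p <- switch(side,
              greater = p_lo,
              less = p_hi,
              two.sided = min(1, 2 * min(p_lo, p_hi)))
  structure(list(p = max(p, 1 / n_boot), estimate = est, distribution = dist,
                 n_boot = n_boot, side = side, null_value = null_value),
            class = "hboot")
}

#' @export
print.hboot <- function(x, ...) {
  cat(sprintf("<hierarchical bootstrap> estimate = %.4g, %s p %s%.4g (n_boot = %d)\n",
              x$estimate, x$side,
              ifelse(x$p <= 1 / x$n_boot, "< ", "= "), x$p, x$n_boot))
  invisible(x)
}

#' TRF power time course
#'
#' Squared TRF magnitude averaged across features (frequencies for
#' spectrograms, phonetic features for phonemes) and across the selected
#' electrodes, per lag, with the standard error computed over electrodes.
#' Power is used because sites respond with either sign; it is invariant to
#' sign flips of the weights.
#'
#' @param fit a fitted [trf()].
#' @param group feature-group name (default: all features).
#' @param electrodes electrode indices to include (default: all).
#' @return list with `lag_ms`, `mean`, `sem`, and `per_electrode`
#'   (electrodes x lags power matrix).
#' @export
trf_power_timecourse <- function(fit, group = NULL, electrodes = NULL) {
  stopifnot(inherits(fit, "trf"))
  electrodes <- electrodes %||% seq_len(fit$n_electrodes)
  if (length(electrodes) == 0L) stop("empty electrode set")
  feats <- if (is.null(group)) seq_len(dim(fit$weights)[2])
           else which(fit$group_of_feature == match(group, fit$group_names))
  if (length(feats) == 0L) stop("no such group: ", group)
  w <- fit$weights[, feats, electrodes, drop = FALSE]
  per_el <- t(apply(w^2, c(1L, 3L), mean))       # electrodes x lags
  m <- colMeans(per_el)
  sem <- apply(per_el, 2L, stats::sd) / sqrt(nrow(per_el))
  list(lag_ms = fit$lag_ms, mean = m, sem = sem, per_electrode = per_el)
}

# band-limited 2x upsampling via FFT with mirror extension (reduces edge
# ringing for short aperiodic curves)
upsample2 <- function(x) {
  n <- length(x)
  ext <- c(x, rev(x))
  X <- stats::fft(ext)
  n2 <- length(ext)
  half <- n2 %/% 2
  Xup <- complex(2 * n2)
  Xup[1:half] <- X[1:half]
  Xup[(2 * n2 - half + 1):(2 * n2)] <- X[(n2 - half + 1):n2]
  if (n2 %% 2 == 0) {
    Xup[half + 1] <- X[half + 1] / 2
    Xup[2 * n2 - half + 1] <- X[half + 1] / 2
  }
  up <- Re(stats::fft(Xup, inverse = TRUE)) / n2
  up[1:(2 * n - 1)]
}

#' Encoding latency from a TRF power curve
#'
#' Upsamples the lag-axis power curve by a factor of 2 (band-limited) and
#' returns the lag of its global maximum; with a 100 Hz frame rate this
#' gives 5 ms resolution. Ties break to the earliest peak; a flat curve has
#' no defined latency and returns `NA`.
#'
#' @param power numeric power curve over lags (e.g., `$mean` or one row of
#'   `$per_electrode` from [trf_power_timecourse()]).
#' @param lag_ms lag axis in ms, same length as `power`.
#' @return latency in ms, or `NA_real_` for a flat curve.
#' @export
encoding_latency <- function(power, lag_ms) {
  stopifnot(length(power) == length(lag_ms), length(power) >= 4L)
  if (stats::sd(power) < .Machine$double.eps) return(NA_real_)
  up <- upsample2(power)
  lag_up <- seq(lag_ms[1], lag_ms[length(lag_ms)], length.out = length(up))
  lag_up[which(up >= max(up) - 1e-12)[1]]   # earliest peak on ties
}

#' Per-lag significance of a TRF power curve against shuffled-feature TRFs
#'
#' At each lag, the per-electrode difference between true power and the mean
#' of the shuffled-feature powers is tested with a one-sided hierarchical
#' bootstrap; lags with `p < alpha` are flagged.
#'
#' @param true_power electrodes x lags matrix of true TRF power.
#' @param shuffled_powers electrodes x lags x n_shuffles array.
#' @param subjects subject tag per electrode.
#' @param n_boot bootstrap iterates per lag (default 1000).
#' @param alpha flag threshold (default 0.05).
#' @param seed integer seed.
#' @return list with logical `significant` per lag and numeric `p` per lag.
#' @export
timecourse_significance <- function(true_power, shuffled_powers, subjects,
                                    n_boot = 1000, alpha = 0.05, seed = NULL) {
  stopifnot(length(dim(shuffled_powers)) == 3L,
            nrow(true_power) == dim(shuffled_powers)[1],
            ncol(true_power) == dim(shuffled_powers)[2])
  shuf_mean <- apply(shuffled_powers, c(1L, 2L), mean)
  nl <- ncol(true_power)
  p <- vapply(seq_len(nl), function(l) {
    d <- true_power[, l] - shuf_mean[, l]
    if (all(d == 0)) return(1)
    hierarchical_bootstrap(d, subjects, n_boot = n_boot,
                           seed = if (is.null(seed)) NULL else seed + l,
                           side = "greater")$p
  }, numeric(1))
  list(significant = p < alpha, p = p)
}

#' Compare glimpsed and masked encoding latencies
#'
#' Unpaired comparison by Wilcoxon rank-sum over all supplied latencies,
#' plus a paired analysis on electrodes appearing in both sets (indices
#' given by `pairing`): one-sample t test on the differences and a
#' hierarchical bootstrap of the mean difference.
#'
#' @param glimpsed_latencies,masked_latencies latency vectors in ms (from
#'   electrodes significantly encoding the respective feature).
#' @param pairing optional 2-column matrix of indices into the two vectors
#'   selecting paired electrodes; defaults to positional pairing when the
#'   vectors have equal length.
#' @param subjects subject tag per *paired* electrode (required for the
#'   bootstrap p).
#' @param n_boot bootstrap iterates (default 10000).
#' @param seed integer seed.
#' @return list with `ranksum_p` (two-sided), `median_glimpsed`,
#'   `median_masked`, `mean_difference_ms`, `t`, `t_p` (one-sided, masked >
#'   glimpsed), `boot_p`, `n_paired`. Entries are `NA` when fewer than 3
#'   electrodes are available for that analysis.
#' @export
latency_comparison <- function(glimpsed_latencies, masked_latencies,
                               pairing = NULL, subjects = NULL,
                               n_boot = 10000, seed = NULL) {
  gl <- glimpsed_latencies[!is.na(glimpsed_latencies)]
  ma <- masked_latencies[!is.na(masked_latencies)]
  ranksum_p <- if (length(gl) >= 3L && length(ma) >= 3L) {
    suppressWarnings(stats::wilcox.test(ma, gl)$p.value)
  } else NA_real_
  if (is.null(pairing) &&
      length(glimpsed_latencies) == length(masked_latencies)) {
    pairing <- cbind(seq_along(glimpsed_latencies),
                     seq_along(masked_latencies))
  }
  mean_diff <- t_stat <- t_p <- boot_p <- NA_real_
  n_paired <- 0L
  if (!is.null(pairing)) {
    d <- masked_latencies[pairing[, 2]] - glimpsed_latencies[pairing[, 1]]
    keep <- !is.na(d)
    d <- d[keep]
    n_paired <- length(d)
    if (n_paired >= 3L) {
      mean_diff <- mean(d)
      if (stats::sd(d) > 1e-9 * max(1, abs(mean_diff))) {
        tt <- stats::t.test(d, alternative = "greater")
        t_stat <- unname(tt$statistic)
        t_p <- tt$p.value
      } else {
        t_stat <- Inf * sign(mean_diff)
        t_p <- if (mean_diff > 0) 0 else 1
      }
      if (!is.null(subjects)) {
        boot_p <- hierarchical_bootstrap(d, subjects[keep], n_boot = n_boot,
                                         seed = seed, side = "greater")$p
      }
    }
  }
  list(ranksum_p = ranksum_p,
       median_glimpsed = if (length(gl)) stats::median(gl) else NA_real_,
       median_masked = if (length(ma)) stats::median(ma) else NA_real_,
       mean_difference_ms = mean_diff, t = t_stat, t_p = t_p,
       boot_p = boot_p, n_paired = n_paired)
}

#' Anatomical gradient of feature encoding
#'
#' Spearman correlation between an anatomical coordinate (e.g.,
#' posterior-anterior position, or distance from the pSTG-mSTG boundary) and
#' each electrode's prediction improvement, with significance from a
#' hierarchical bootstrap of the correlation itself.
#'
#' @param delta_z prediction improvement per electrode.
#' @param coordinate anatomical scalar per electrode.
#' @param subjects subject tag per electrode.
#' @param n_boot bootstrap iterates (default 10000).
#' @param seed integer seed.
#' @param side p-value sidedness (default two-sided).
#' @return list with `rho`, `p`, `n`, and the bootstrap object.
#' @export
anatomical_correlation <- function(delta_z, coordinate, subjects,
                                   n_boot = 10000, seed = NULL,
                                   side = "two.sided") {
  stopifnot(length(delta_z) == length(coordinate))
  if (length(delta_z) < 5L) stop("need at least 5 electrodes with coordinates")
  if (stats::sd(coordinate) < .Machine$double.eps) {
    stop("constant coordinate; Spearman correlation undefined")
  }
  rho <- stats::cor(coordinate, delta_z, method = "spearman")
  df <- data.frame(coordinate = coordinate, delta_z = delta_z)
  hb <- hierarchical_bootstrap(
    df, subjects,
    statistic = function(d) {
      if (stats::sd(d$coordinate) < .Machine$double.eps) return(0)
      stats::cor(d$coordinate, d$delta_z, method = "spearman")
    },
    n_boot = n_boot, seed = seed, side = side
  )
  list(rho = rho, p = hb$p, n = length(delta_z), boot = hb)
}
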