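# Banded ridge temporal response functions: lagged design construction,
# the exact banded-ridge solver, sequential lambda tuning (polar search for
# the first pair, 1-D log grids thereafter), and contiguous-block
# cross-validated evaluation in Fisher-z units.

#' Convert a lag range in ms to integer frame lags
#' @param lags_ms length-2 numeric, e.g. `c(0, 500)` or `c(-100, 600)`.
#' @param frame_rate_hz frame rate.
#' @return integer vector of frame lags (positive = past stimulus).
#' @export
lag_frames <- function(lags_ms = c(0, 500), frame_rate_hz = 100) {
  stopifnot(length(lags_ms) == 2L, lags_ms[1] <= lags_ms[2])
  seq.int(as.integer(round(lags_ms[1] * frame_rate_hz / 1000)),
          as.integer(round(lags_ms[2] * frame_rate_hz / 1000)))
}

#' Build a lagged (Toeplitz) design matrix
#'
#' Column `(f, l)` at row `t` holds feature `f` at time `t - l`; out-of-range
#' samples are zero. Columns are ordered feature-major with lag varying
#' fastest, so a fitted weight vector reshapes to a `lags x features` array
#' directly. A negative lag anticipates the feature.
#'
#' @param x time x features matrix (a vector is treated as one feature).
#' @param lags integer frame lags from [lag_frames()].
#' @return time x (features * lags) matrix.
#' @export
build_lagged_design <- function(x, lags) {
  x <- as.matrix(x)
  nt <- nrow(x); p <- ncol(x); nl <- length(lags)
  if (p == 0L) stop("empty feature matrix")
  out <- matrix(0, nt, p * nl)
  for (j in seq_len(p)) {
    for (i in seq_len(nl)) {
      l <- lags[i]
      col <- (j - 1L) * nl + i
      if (l >= 0L) {
        if (l < nt) out[(l + 1L):nt, col] <- x[1:(nt - l), j]
      } else {
        if (-l < nt) out[1:(nt + l), col] <- x[(1L - l):nt, j]
      }
    }
  }
  cn <- colnames(x) %||% paste0("f", seq_len(p))
  colnames(out) <- paste0(rep(cn, each = nl), "@", rep(lags, p))
  out
}

#' Solve banded ridge regression exactly
#'
#' Returns the minimizer of `||y - Xw||^2 + w' L w` with `L` diagonal,
#' carrying penalty `lambda_g` on every column of group `g` — mass-univariate
#' across response columns (shared design). Solved through the penalized
#' normal equations; numerically equivalent (tested to 1e-8) to the
#' column-rescaling single-SVD route, which [tune_lambdas_sequential()] uses
#' where its reuse across penalty scales pays off.
#'
#' @param design time x p matrix (already lagged).
#' @param response time x electrodes matrix (or vector).
#' @param lambda_per_col numeric length p (or scalar) of nonnegative
#'   penalties.
#' @return p x electrodes weight matrix.
#' @export
fit_banded_ridge <- function(design, response, lambda_per_col) {
  response <- as.matrix(response)
  if (!all(is.finite(design)) || !all(is.finite(response))) {
    stop("design and response must be finite")
  }
  p <- ncol(design)
  lam <- rep_len(lambda_per_col, p)
  C <- crossprod(design)
  b <- crossprod(design, response)
  w <- solve_ridge_normal(C, b, lam)
  rownames(w) <- colnames(design)
  w
}

# chol solve of (C + diag(lam)) w = b, falling back to an eigendecomposition
# if the penalized Gram matrix is numerically singular
solve_ridge_normal <- function(C, b, lam) {
  A <- C
  diag(A) <- diag(A) + lam
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(ch)) {
    backsolve(ch, forwardsolve(t(ch), b))
  } else {
    e <- eigen(A, symmetric = TRUE)
    d <- pmax(e$values, max(e$values) * 1e-12)
    e$vectors %*% ((crossprod(e$vectors, b)) / d)
  }
}

# ---- internal cross-validation machinery ---------------------------------

# contiguous-block fold ids over nt frames
fold_ids <- function(nt, n_folds) {
  rep(seq_len(n_folds), each = ceiling(nt / n_folds))[seq_len(nt)]
}

# Per-fold sufficient statistics for a bank: features are z-scored on the
# training frames (before lagging), the response is centred on training
# frames, and test frames within one lag span of a fold edge are excluded
# from scoring to avoid leakage through lagged copies.
cv_prepare <- function(bank, response, lags, n_folds) {
  X <- do.call(cbind, bank$groups)
  group_sizes <- vapply(bank$groups, ncol, integer(1))
  group_of_feature <- rep(seq_along(bank$groups), group_sizes)
  nl <- length(lags)
  group_of_col <- rep(group_of_feature, each = nl)
  Y <- as.matrix(response)
  nt <- nrow(X)
  stopifnot(nrow(Y) == nt)
  ids <- fold_ids(nt, n_folds)
  span_lo <- max(0L, max(lags))
  span_hi <- max(0L, -min(lags))
  folds <- lapply(seq_len(n_folds), function(k) {
    train <- which(ids != k)
    test <- which(ids == k)
    if (length(test) <= span_lo + span_hi + 2L) {
      stop("folds too short for the requested lag span")
    }
    sc <- scale_columns(X[train, , drop = FALSE])
    Xs <- scale_columns(X, sc$center, sc$scale)$x
    D <- build_lagged_design(Xs, lags)
    ycenter <- colMeans(Y[train, , drop = FALSE])
    score <- test[test >= min(test) + span_lo & test <= max(test) - span_hi]
    list(
      C = crossprod(D[train, , drop = FALSE]),
      b = crossprod(D[train, , drop = FALSE],
                    sweep(Y[train, , drop = FALSE], 2L, ycenter, "-")),
      Xtest = D[score, , drop = FALSE],
      Ytest = Y[score, , drop = FALSE]
    )
  })
  list(folds = folds, group_of_col = group_of_col,
       group_names = names(bank$groups), n_col = ncol(X) * nl)
}

# per-electrode Fisher z for one fold given solved weights
fold_z <- function(fold, w) {
  pred <- fold$Xtest %*% w
  vapply(seq_len(ncol(w)), function(e) {
    p <- pred[, e]; y <- fold$Ytest[, e]
    if (stats::sd(p) < .Machine$double.eps ||
        stats::sd(y) < .Machine$double.eps) return(NA_real_)
    atanh(min(max(stats::cor(p, y), -1 + 1e-12), 1 - 1e-12))
  }, numeric(1))
}

cv_evaluate <- function(prep, lambdas_by_group) {
  lam <- lambdas_by_group[prep$group_of_col]
  z <- t(vapply(prep$folds, function(f) {
    fold_z(f, solve_ridge_normal(f$C, f$b, lam))
  }, numeric(ncol(prep$folds[[1]]$Ytest))))
  if (anyNA(z)) {
    warning("undefined correlation in ", sum(is.na(z)),
            " fold x electrode cell(s); excluded from means")
  }
  z
}

#' Cross-validated prediction accuracy of a banded-ridge TRF model
#'
#' Splits the recording into contiguous time-block folds, fits on the
#' training folds with frozen per-group lambdas, and reports the
#' Fisher-transformed Pearson correlation between predicted and observed
#' responses per electrode and fold. Feature columns are z-scored on
#' training data before lagging; the response is centred per training fold;
#' test frames within one lag span of a fold boundary are not scored.
#'
#' @param bank a [regressor_bank()].
#' @param response time x electrodes matrix.
#' @param lambdas named per-group penalties (defaults to the bank's).
#' @param lags_ms lag range in ms (default `c(0, 500)`).
#' @param n_folds number of folds (default 5).
#' @return list with `z` (folds x electrodes), `mean_z` per electrode
#'   (fold-averaged, `NA` cells excluded), `lags_ms`, `lambdas`.
#' @export
crossval_predict <- function(bank, response, lambdas = NULL,
                             lags_ms = c(0, 500), n_folds = 5) {
  stopifnot(n_folds >= 2L)
  lambdas <- resolve_lambdas(bank, lambdas)
  lags <- lag_frames(lags_ms, bank$frame_rate_hz)
  X <- do.call(cbind, bank$groups)
  group_sizes <- vapply(bank$groups, ncol, integer(1))
  lam_col <- rep(lambdas[rep(seq_along(bank$groups), group_sizes)],
                 each = length(lags))
  Y <- as.matrix(response)
  nt <- nrow(X)
  stopifnot(nrow(Y) == nt)
  ids <- fold_ids(nt, n_folds)
  span_lo <- max(0L, max(lags))
  span_hi <- max(0L, -min(lags))
  # streamed per fold: build the fold's standardized lagged design, take
  # sufficient statistics, solve, score, and release before the next fold
  z <- matrix(NA_real_, n_folds, ncol(Y))
  for (k in seq_len(n_folds)) {
    train <- which(ids != k)
    test <- which(ids == k)
    if (length(test) <= span_lo + span_hi + 2L) {
      stop("folds too short for the requested lag span")
    }
    sc <- scale_columns(X[train, , drop = FALSE])
    D <- build_lagged_design(scale_columns(X, sc$center, sc$scale)$x, lags)
    score <- test[test >= min(test) + span_lo & test <= max(test) - span_hi]
    Dtest <- D[score, , drop = FALSE]
    boundary <- setdiff(test, score)
    C <- crossprod(D) - crossprod(Dtest)
    if (length(boundary)) C <- C - crossprod(D[boundary, , drop = FALSE])
    ycenter <- colMeans(Y[train, , drop = FALSE])
    Yz <- sweep(Y, 2L, ycenter, "-")
    Yz[test, ] <- 0                      # test rows contribute nothing to b
    b <- crossprod(D, Yz)
    rm(D); gc(FALSE)
    w <- solve_ridge_normal(C, b, lam_col)
    z[k, ] <- fold_z(list(Xtest = Dtest, Ytest = Y[score, , drop = FALSE]), w)
    rm(Dtest, C, b, w); gc(FALSE)
  }
  if (anyNA(z)) {
    warning("undefined correlation in ", sum(is.na(z)),
            " fold x electrode cell(s); excluded from means")
  }
  list(z = z, mean_z = colMeans(z, na.rm = TRUE), lags_ms = lags_ms,
       lambdas = lambdas, n_folds = n_folds)
}

resolve_lambdas <- function(bank, lambdas) {
  lam <- bank$lambdas
  if (!is.null(lambdas)) lam[names(lambdas)] <- lambdas
  if (anyNA(lam)) {
    stop("missing lambda(s) for group(s): ",
         paste(names(lam)[is.na(lam)], collapse = ", "))
  }
  lam
}

#' Sequential lambda tuning with an initial polar search
#'
#' Stage 1 jointly tunes the penalties of the first two groups by a polar
#' grid search: the ratio of the two lambdas is parameterized by an angle
#' and their common scale by a radius, so one eigendecomposition of the
#' rescaled Gram matrix per (fold, angle) serves every radius. Remaining
#' groups are then tuned one at a time over a log-spaced grid with all
#' earlier lambdas frozen, in bank order; each group's lambda is frozen once
#' chosen and shared across all subsequent models and electrodes. The
#' objective is the mean cross-validated Fisher z over electrodes; ties
#' break toward heavier regularization.
#'
#' @param bank a [regressor_bank()]; group order is the tuning order and the
#'   first two groups form the polar pair.
#' @param response time x electrodes matrix.
#' @param lags_ms lag range in ms.
#' @param n_folds CV folds (default 5).
#' @param n_angles number of angles uniformly interior to `(0, pi/2)`.
#' @param radii radius grid (default `10^seq(-2, 5, by = 0.5)`).
#' @param grid 1-D lambda grid for later stages
#'   (default `10^seq(-2, 5, length.out = 25)`).
#' @return named numeric vector of tuned lambdas (also a `"trace"` attribute
#'   with the per-stage objective values).
#' @export
tune_lambdas_sequential <- function(bank, response, lags_ms = c(0, 500),
                                    n_folds = 5, n_angles = 17,
                                    radii = 10^seq(-2, 5, by = 0.5),
                                    grid = 10^seq(-2, 5, length.out = 25)) {
  ng <- length(bank$groups)
  lags <- lag_frames(lags_ms, bank$frame_rate_hz)
  lam <- stats::setNames(rep(NA_real_, ng), names(bank$groups))
  trace <- list()

  # stage 1: polar search over the first pair (or a plain grid if only one)
  if (ng == 1L) {
    sub <- regressor_bank(bank$groups[1], bank$frame_rate_hz)
    prep <- cv_prepare(sub, response, lags, n_folds)
    obj <- vapply(grid, function(l) {
      mean(cv_evaluate_quiet(prep, l), na.rm = TRUE)
    }, numeric(1))
    lam[1] <- grid[pick_max(obj)]
    trace$stage1 <- obj
  } else {
    sub <- regressor_bank(bank$groups[1:2], bank$frame_rate_hz)
    prep <- cv_prepare(sub, response, lags, n_folds)
    angles <- pi / 2 * seq_len(n_angles) / (n_angles + 1)
    obj <- matrix(NA_real_, length(angles), length(radii))
    for (ai in seq_along(angles)) {
      u <- c(cos(angles[ai]), sin(angles[ai]))[prep$group_of_col]
      zsum <- 0
      for (f in prep$folds) {
        d_inv <- 1 / sqrt(u)
        Cs <- f$C * tcrossprod(d_inv)     # D C D
        e <- eigen(Cs, symmetric = TRUE)
        bs <- crossprod(e$vectors, f$b * d_inv)
        M <- (sweep(f$Xtest, 2L, d_inv, "*")) %*% e$vectors
        for (ri in seq_along(radii)) {
          wtil <- bs / (pmax(e$values, 0) + radii[ri])
          pred <- M %*% wtil
          zf <- vapply(seq_len(ncol(pred)), function(el) {
            p <- pred[, el]; y <- f$Ytest[, el]
            if (stats::sd(p) < .Machine$double.eps) return(NA_real_)
            atanh(min(max(stats::cor(p, y), -1 + 1e-12), 1 - 1e-12))
          }, numeric(1))
          obj[ai, ri] <- sum(obj[ai, ri], mean(zf, na.rm = TRUE), na.rm = TRUE)
        }
      }
    }
    obj <- obj / length(prep$folds)
    best <- which(obj == max(obj), arr.ind = TRUE)
    best <- best[order(best[, 2], decreasing = TRUE)[1], ]  # tie: larger radius
    if (best[2] %in% c(1L, length(radii))) {
      warning("polar-search optimum at the radius grid boundary; ",
              "the true optimum may lie outside the grid")
    }
    lam[1] <- radii[best[2]] * cos(angles[best[1]])
    lam[2] <- radii[best[2]] * sin(angles[best[1]])
    trace$stage1 <- obj
  }

  # later stages: one group at a time, earlier lambdas frozen
  start <- if (ng == 1L) 2L else 3L
  if (start <= ng) {
    for (g in start:ng) {
      sub <- regressor_bank(bank$groups[1:g], bank$frame_rate_hz)
      prep <- cv_prepare(sub, response, lags, n_folds)
      obj <- vapply(grid, function(cand) {
        lam_g <- c(lam[1:(g - 1L)], cand)
        mean(cv_evaluate_quiet(prep, lam_g), na.rm = TRUE)
      }, numeric(1))
      if (pick_max(obj) %in% c(1L, length(grid))) {
        warning("lambda grid optimum at boundary for group ",
                names(bank$groups)[g])
      }
      lam[g] <- grid[pick_max(obj)]
      trace[[names(bank$groups)[g]]] <- obj
    }
  }
  attr(lam, "trace") <- trace
  lam
}

cv_evaluate_quiet <- function(prep, lambdas_by_group) {
  suppressWarnings(cv_evaluate(prep, lambdas_by_group))
}

# index of the maximum, breaking ties toward the larger (later) grid value
pick_max <- function(x) {
  m <- max(x)
  max(which(x >= m - 1e-12))
}

# ---- the model-object interface ------------------------------------------

#' Fit a banded-ridge temporal response function model
#'
#' The package's central fitting function: maps a bank of lagged stimulus
#' feature groups to multi-electrode neural responses by banded ridge
#' regression. Per-group penalties may be supplied (e.g.,
#' [lambda_defaults()]), taken from the bank, or tuned here via
#' [tune_lambdas_sequential()]. Cross-validated Fisher-z prediction
#' accuracies are computed with contiguous-block folds, and the final
#' weights are refit on the full recording with features z-scored globally.
#'
#' @param bank a [regressor_bank()].
#' @param response time x electrodes matrix of z-scored envelopes.
#' @param lambdas named per-group penalties; `NULL` uses the bank's, or
#'   tunes them when `tune = TRUE`.
#' @param lags_ms lag range in ms (default `c(0, 500)`; use `c(-100, 600)`
#'   for display-oriented fits).
#' @param n_folds CV folds (default 5).
#' @param tune logical; tune lambdas sequentially before fitting.
#' @param cv logical; set `FALSE` to skip cross-validation and only fit
#'   full-data weights.
#' @param ... passed to [tune_lambdas_sequential()] when tuning.
#' @return an object of class `trf`: list with `weights` (array lags x
#'   features x electrodes), `lag_ms` axis, `cv` (the [crossval_predict()]
#'   result or `NULL`), `lambdas`, `group_of_feature`, `feature_names`,
#'   `group_names`.
#' @export
trf <- function(bank, response, lambdas = NULL, lags_ms = c(0, 500),
                n_folds = 5, tune = FALSE, cv = TRUE, ...) {
  response <- as.matrix(response)
  if (tune) {
    lambdas <- tune_lambdas_sequential(bank, response, lags_ms = lags_ms,
                                       n_folds = n_folds, ...)
  }
  lam <- resolve_lambdas(bank, lambdas)
  lags <- lag_frames(lags_ms, bank$frame_rate_hz)
  cvres <- if (cv) crossval_predict(bank, response, lam, lags_ms, n_folds)
           else NULL

  X <- do.call(cbind, bank$groups)
  group_sizes <- vapply(bank$groups, ncol, integer(1))
  group_of_feature <- rep(seq_along(bank$groups), group_sizes)
  sc <- scale_columns(X)
  D <- build_lagged_design(sc$x, lags)
  lam_col <- lam[rep(group_of_feature, each = length(lags))]
  w <- fit_banded_ridge(D, sweep(response, 2L, colMeans(response), "-"),
                        lam_col)
  rm(D); gc(FALSE)
  nl <- length(lags)
  weights <- array(w, dim = c(nl, ncol(X), ncol(response)))
  feature_names <- unlist(lapply(seq_along(bank$groups), function(g) {
    cn <- colnames(bank$groups[[g]]) %||%
      paste0("f", seq_len(ncol(bank$groups[[g]])))
    paste(names(bank$groups)[g], cn, sep = ".")
  }), use.names = FALSE)
  dimnames(weights) <- list(NULL, feature_names,
                            colnames(response) %||%
                              paste0("e", seq_len(ncol(response))))
  structure(
    list(weights = weights, lag_ms = lags * 1000 / bank$frame_rate_hz,
         cv = cvres, lambdas = lam, group_of_feature = group_of_feature,
         group_names = names(bank$groups), feature_names = feature_names,
         frame_rate_hz = bank$frame_rate_hz, n_electrodes = ncol(response)),
    class = "trf"
  )
}

#' @export
print.trf <- function(x, ...) {
  cat(sprintf("<trf> %d lag(s) [%g..%g ms] x %d feature(s) x %d electrode(s)\n",
              length(x$lag_ms), min(x$lag_ms), max(x$lag_ms),
              dim(x$weights)[2], x$n_electrodes))
  if (!is.null(x$cv)) {
    cat(sprintf("  mean CV Fisher z: %.4f (range %.4f..%.4f over electrodes)\n",
                mean(x$cv$mean_z, na.rm = TRUE),
                min(x$cv$mean_z, na.rm = TRUE),
                max(x$cv$mean_z, na.rm = TRUE)))
  }
  cat("  groups:", paste(x$group_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.trf <- function(object, ...) {
  out <- list(
    lambdas = object$lambdas,
    mean_z = if (!is.null(object$cv)) object$cv$mean_z else NULL,
    group_power = vapply(seq_along(object$group_names), function(g) {
      mean(object$weights[, object$group_of_feature == g, , drop = FALSE]^2)
    }, numeric(1))
  )
  names(out$group_power) <- object$group_names
  class(out) <- "summary.trf"
  out
}

#' @export
print.summary.trf <- function(x, ...) {
  cat("Banded ridge TRF summary\n\nPer-group lambda and mean weight power:\n")
  print(data.frame(lambda = x$lambdas, power = x$group_power))
  if (!is.null(x$mean_z)) {
    cat(sprintf("\nCV Fisher z over electrodes: mean %.4f, median %.4f\n",
                mean(x$mean_z, na.rm = TRUE),
                stats::median(x$mean_z, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
coef.trf <- function(object, ...) object$weights

#' Predict responses from a fitted TRF
#'
#' @param object a fitted `trf`.
#' @param bank a [regressor_bank()] with the same groups (possibly new data).
#' @param ... unused.
#' @return time x electrodes matrix of predicted (centred) responses.
#' @export
predict.trf <- function(object, bank, ...) {
  stopifnot(identical(names(bank$groups), object$group_names))
  X <- do.call(cbind, bank$groups)
  sc <- scale_columns(X)
  D <- build_lagged_design(sc$x, lag_frames(range(object$lag_ms),
                                            bank$frame_rate_hz))
  nl <- length(object$lag_ms)
  w <- matrix(object$weights, nrow = nl * dim(object$weights)[2])
  D %*% w
}

#' Plot the power time course of a fitted TRF
#'
#' @param x a fitted `trf`.
#' @param group group name to display (default: all features).
#' @param ... passed to [graphics::plot()].
#' @export
plot.trf <- function(x, group = NULL, ...) {
  pw <- trf_power_timecourse(x, group = group)
  graphics::plot(pw$lag_ms, pw$mean, type = "l", xlab = "lag (ms)",
                 ylab = "TRF power", ...)
  graphics::polygon(c(pw$lag_ms, rev(pw$lag_ms)),
                    c(pw$mean + pw$sem, rev(pw$mean - pw$sem)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(pw$lag_ms, pw$mean)
  invisible(x)
}
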