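#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a child seed from a parent seed and a stage label
#'
#' Deterministic fan-out of one top-level seed into per-stage seeds, so
#' pipeline stages can be rerun in isolation with reproducible randomness.
#' The child is a 31-bit integer (safe for `set.seed`).
#'
#' @param seed parent integer seed.
#' @param label character stage label.
#' @return integer child seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  h <- sum(as.integer(charToRaw(label)) * seq_along(charToRaw(label)))
  as.integer((as.double(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

#' Fisher z-transform of a correlation
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @return `atanh(r)`; values with `|r| = 1` map to `+/-Inf`.
#' @export
fisher_z <- function(r) atanh(r)

# column-wise z-score using supplied (or own) stats; constant columns pass
# through centred with unit scale so downstream algebra stays finite
scale_columns <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2L, stats::sd)
    scale[!is.finite(scale) | scale < .Machine$double.eps] <- 1
  }
  out <- sweep(x, 2L, center, "-")
  out <- sweep(out, 2L, scale, "/")
  list(x = out, center = center, scale = scale)
}

#' Analytic-signal magnitude (Hilbert envelope)
#'
#' FFT implementation of the analytic signal; returns `Mod(x + i*H(x))`.
#'
#' @param x numeric vector.
#' @return nonnegative envelope, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

frame_count <- function(duration_s, frame_rate_hz) {
  as.integer(ceiling(duration_s * frame_rate_hz - 1e-9))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
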