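#' Log-spaced filterbank band edges and centers
#'
#' Bands partition `[fmin, fmax]` into `n_bands` contiguous intervals with
#' logarithmically spaced edges; each band's center is the geometric mean of
#' its edges, so centers are log-uniform and strictly increasing.
#'
#' @param n_bands number of bands.
#' @param fmin_hz,fmax_hz frequency range in Hz.
#' @return list with `edges` (length `n_bands + 1`) and `centers`
#'   (length `n_bands`), both in Hz.
#' @export
band_partition <- function(n_bands, fmin_hz = 50, fmax_hz = 8000) {
  stopifnot(n_bands >= 1, fmin_hz > 0, fmax_hz > fmin_hz)
  edges <- exp(seq(log(fmin_hz), log(fmax_hz), length.out = n_bands + 1L))
  list(edges = edges, centers = sqrt(edges[-1] * edges[-length(edges)]))
}

new_band_spectrogram <- function(values, band_centers_hz, frame_rate_hz) {
  stopifnot(is.matrix(values), ncol(values) == length(band_centers_hz))
  if (any(values < 0)) stop("spectrogram values must be nonnegative")
  if (is.unsorted(band_centers_hz, strictly = TRUE)) {
    stop("band centers must be strictly increasing")
  }
  structure(
    list(values = values, band_centers_hz = band_centers_hz,
         frame_rate_hz = frame_rate_hz),
    class = "band_spectrogram"
  )
}

#' @export
print.band_spectrogram <- function(x, ...) {
  cat(sprintf("<band_spectrogram> %d frames x %d bands @ %g Hz, %.0f-%.0f Hz\n",
              nrow(x$values), ncol(x$values), x$frame_rate_hz,
              min(x$band_centers_hz), max(x$band_centers_hz)))
  invisible(x)
}

#' Multiband magnitude spectrogram of a waveform
#'
#' Splits the signal into `n_bands` log-spaced bands (bandpass Butterworth
#' filters applied forward-backward), takes the Hilbert-envelope magnitude of
#' each band, and averages samples within consecutive frames to reach the
#' target frame rate. Values are linear magnitudes (not dB), hence
#' nonnegative, which the downstream glimpsed/masked edge algebra requires.
#'
#' @param waveform numeric vector of audio samples (mono).
#' @param fs sampling rate in Hz.
#' @param n_bands number of frequency bands (10 for TRF regressors, 100 for
#'   glimpse ratios).
#' @param fmin_hz,fmax_hz band range; `fmax_hz` must not exceed Nyquist.
#' @param frame_rate_hz output frame rate (default 100).
#' @param filter_order Butterworth section order per edge (default 2, i.e.,
#'   a 4th-order bandpass).
#' @return a `band_spectrogram` with `ceiling(duration * frame_rate)` frames.
#' @export
compute_band_spectrogram <- function(waveform, fs, n_bands = 10,
                                     fmin_hz = 50, fmax_hz = 8000,
                                     frame_rate_hz = 100, filter_order = 2) {
  stopifnot(is.numeric(waveform), all(is.finite(waveform)), fs > 0)
  if (fmax_hz > fs / 2) stop("fmax_hz above Nyquist frequency")
  n <- length(waveform)
  if (n < fs / frame_rate_hz) stop("waveform shorter than one frame")
  nframes <- frame_count(n / fs, frame_rate_hz)
  bp <- band_partition(n_bands, fmin_hz, fmax_hz)
  # frame membership: frame t (1-based) owns samples in [(t-1)*fs/rate, t*fs/rate)
  frame_of <- pmin(floor((seq_len(n) - 1) * frame_rate_hz / fs) + 1L, nframes)
  vals <- matrix(0, nframes, n_bands)
  if (any(waveform != 0)) {
    for (b in seq_len(n_bands)) {
      w <- c(bp$edges[b], bp$edges[b + 1L]) / (fs / 2)
      w <- pmin(pmax(w, 1e-6), 1 - 1e-6)
      flt <- signal::butter(filter_order, w, type = "pass")
      xb <- signal::filtfilt(flt, waveform)
      env <- hilbert_envelope(xb)
      vals[, b] <- as.numeric(tapply(env, frame_of, mean))
    }
  }
  vals[vals < 0] <- 0
  new_band_spectrogram(vals, bp$centers, frame_rate_hz)
}

#' Acoustic edges: half-wave rectified temporal derivative
#'
#' `out[t, b] = max(spec[t, b] - spec[t - 1, b], 0)` with the first frame
#' defined as 0 (no predecessor). Invariant to constant spectral offsets.
#'
#' @param spec a `band_spectrogram` or a nonnegative time-by-band matrix.
#' @return matrix of the same shape as the input values.
#' @export
compute_edges <- function(spec) {
  v <- if (inherits(spec, "band_spectrogram")) spec$values else spec
  stopifnot(is.matrix(v))
  out <- rbind(0, diff(v))
  out[out < 0] <- 0
  dimnames(out) <- dimnames(v)
  out
}

#' Split a talker's edges into glimpsed and masked components
#'
#' Glimpsed edges are the part of a talker's acoustic edges also present in
#' the mixture, `min(edge_talker, edge_mixture)`; masked edges are the excess
#' over the mixture, `max(edge_talker - edge_mixture, 0)`. The two components
#' always reconstruct the talker's edges exactly.
#'
#' @param talker_edges,mixture_edges nonnegative matrices of equal shape.
#' @return list of class `edge_set` with elements `raw`, `glimpsed`, `masked`.
#' @export
decompose_edges <- function(talker_edges, mixture_edges) {
  if (!identical(dim(talker_edges), dim(mixture_edges))) {
    stop("talker and mixture edge matrices must have the same shape")
  }
  if (any(talker_edges < 0) || any(mixture_edges < 0)) {
    stop("edge matrices must be nonnegative")
  }
  glimpsed <- pmin(talker_edges, mixture_edges)
  masked <- talker_edges - glimpsed      # == pmax(talker - mixture, 0)
  structure(list(raw = talker_edges, glimpsed = glimpsed, masked = masked),
            class = "edge_set")
}

#' Locally time-shuffle a feature matrix
#'
#' Permutes rows (all columns together) independently within consecutive
#' windows of `window_ms`, preserving local and global statistics while
#' destroying the time-locked stimulus-response relationship. A window longer
#' than the signal shuffles the whole signal as one window.
#'
#' @param x time-by-feature matrix.
#' @param window_ms window length in milliseconds (default 500).
#' @param frame_rate_hz frame rate of the time axis.
#' @param seed integer seed; the same seed reproduces the same shuffle.
#' @return matrix of the same shape with rows permuted within windows.
#' @export
shuffle_local <- function(x, window_ms = 500, frame_rate_hz = 100, seed = NULL) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  w <- max(2L, as.integer(round(window_ms / 1000 * frame_rate_hz)))
  if (w > n) w <- n
  starts <- seq.int(1L, n, by = w)
  perm <- with_seed(seed, {
    unlist(lapply(starts, function(s) {
      idx <- s:min(s + w - 1L, n)
      idx[sample.int(length(idx))]
    }))
  })
  x[perm, , drop = FALSE]
}
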