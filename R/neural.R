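# Neural preprocessing: broadband cleanup, high-gamma envelope extraction,
# silence-referenced z-scoring, and speech-responsiveness selection.

# RBJ biquad notch at f0 with the given bandwidth; applied forward-backward
design_notch <- function(f0, bw, fs) {
  w0 <- 2 * pi * f0 / fs
  q <- f0 / bw
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Clean broadband recordings
#'
#' First-order Butterworth high-pass at 1 Hz removes DC drift; second-order
#' IIR notch filters (1 Hz bandwidth) remove line noise at 60 Hz and its
#' harmonics up to 240 Hz. All filters are applied forward and backward
#' (zero phase). If a neighbor map is supplied, each electrode is locally
#' re-referenced by subtracting the mean of its neighbors.
#'
#' @param raw electrodes x time matrix.
#' @param fs sampling rate in Hz.
#' @param line_hz line frequency (default 60); harmonics up to 240 Hz are
#'   notched, skipping (with a warning) any above `fs / 2 * 0.95`.
#' @param neighbor_map optional list, one integer vector of neighbor row
#'   indices per electrode.
#' @param highpass_hz high-pass cutoff (default 1).
#' @return cleaned electrodes x time matrix.
#' @export
preprocess_broadband <- function(raw, fs, line_hz = 60, neighbor_map = NULL,
                                 highpass_hz = 1) {
  stopifnot(is.matrix(raw), fs > 0)
  x <- raw
  if (!is.null(neighbor_map)) {
    stopifnot(length(neighbor_map) == nrow(x))
    ref <- t(vapply(seq_len(nrow(x)), function(e) {
      nb <- neighbor_map[[e]]
      if (length(nb)) colMeans(x[nb, , drop = FALSE]) else numeric(ncol(x))
    }, numeric(ncol(x))))
    x <- x - ref
  }
  hp <- signal::butter(1, highpass_hz / (fs / 2), type = "high")
  harmonics <- line_hz * seq_len(4L)
  usable <- harmonics[harmonics < fs / 2 * 0.95]
  if (length(usable) < length(harmonics)) {
    warning("skipping notch filter(s) above Nyquist: ",
            paste(setdiff(harmonics, usable), collapse = ", "), " Hz")
  }
  notches <- lapply(usable, design_notch, bw = 1, fs = fs)
  for (e in seq_len(nrow(x))) {
    v <- signal::filtfilt(hp, x[e, ])
    for (nf in notches) v <- signal::filtfilt(nf, v)
    x[e, ] <- v
  }
  x
}

#' High-gamma envelope at 100 Hz
#'
#' Filters each electrode into 8 bands of 10 Hz width spanning 70-150 Hz
#' (Chebyshev type II bandpass, order 4, 40 dB stopband, stopband edges
#' placed 5 Hz outside each nominal band), takes the Hilbert
#' magnitude of each band, averages the 8 band envelopes, and resamples to
#' the target rate by frame averaging (boxcar anti-aliasing over exact frame
#' windows, keeping the envelope frame axis aligned with the stimulus
#' spectrogram frames).
#'
#' @param cleaned electrodes x time matrix (output of
#'   [preprocess_broadband()], or any broadband signal).
#' @param fs sampling rate in Hz (must be at least 300).
#' @param band_lo,band_hi high-gamma range (default 70-150 Hz).
#' @param n_bands number of sub-bands (default 8).
#' @param target_rate_hz output rate (default 100).
#' @return electrodes x frames nonnegative envelope matrix.
#' @export
highgamma_envelope <- function(cleaned, fs, band_lo = 70, band_hi = 150,
                               n_bands = 8, target_rate_hz = 100) {
  stopifnot(is.matrix(cleaned), fs >= 300)
  edges <- seq(band_lo, band_hi, length.out = n_bands + 1L)
  # Chebyshev II takes stopband edges: place them 5 Hz outside each nominal
  # band so the band itself is (close to) passband
  margin <- 5
  filters <- lapply(seq_len(n_bands), function(b) {
    w <- c(max(edges[b] - margin, 1), min(edges[b + 1L] + margin, fs / 2 - 1))
    signal::cheby2(4, 40, w / (fs / 2), type = "pass")
  })
  n <- ncol(cleaned)
  nframes <- frame_count(n / fs, target_rate_hz)
  frame_of <- pmin(floor((seq_len(n) - 1) * target_rate_hz / fs) + 1L, nframes)
  out <- matrix(0, nrow(cleaned), nframes)
  for (e in seq_len(nrow(cleaned))) {
    if (all(cleaned[e, ] == 0)) next
    env <- numeric(n)
    for (flt in filters) {
      env <- env + hilbert_envelope(signal::filtfilt(flt, cleaned[e, ]))
    }
    env <- env / n_bands
    out[e, ] <- as.numeric(tapply(env, frame_of, mean))
  }
  out
}

#' Z-score envelopes against a pre-stimulus silence period
#'
#' Subtracts the mean and divides by the standard deviation of the silent
#' frames, per electrode, so responses are in units of silent-baseline SD.
#'
#' @param envelope electrodes x frames matrix (a single electrode may be
#'   passed as a vector).
#' @param silence_mask logical vector over frames marking the silence period.
#' @return z-scored matrix of the same shape.
#' @export
zscore_to_silence <- function(envelope, silence_mask) {
  v <- if (is.matrix(envelope)) envelope else matrix(envelope, nrow = 1L)
  stopifnot(length(silence_mask) == ncol(v), any(silence_mask))
  mu <- rowMeans(v[, silence_mask, drop = FALSE])
  sd0 <- apply(v[, silence_mask, drop = FALSE], 1L, stats::sd)
  if (any(!is.finite(sd0) | sd0 < .Machine$double.eps)) {
    stop("zero-variance silence period; cannot z-score")
  }
  out <- (v - mu) / sd0
  if (is.matrix(envelope)) out else drop(out)
}

#' Speech responsiveness by Cohen's D
#'
#' Effect size between response distributions during speech and silence,
#' using the pooled standard deviation. Electrodes with `D` strictly greater
#' than the threshold are retained.
#'
#' @param envelope electrodes x frames matrix.
#' @param speech_mask,silence_mask logical frame masks (nonempty, disjoint
#'   usage expected but not enforced).
#' @param threshold retain electrodes with `D > threshold` (default 0.2, a
#'   small but meaningful effect).
#' @return data frame with `cohens_d` and logical `keep` per electrode;
#'   electrodes with degenerate pooled SD get `NA` and are dropped with a
#'   warning.
#' @export
speech_responsiveness <- function(envelope, speech_mask, silence_mask,
                                  threshold = 0.2) {
  stopifnot(is.matrix(envelope), any(speech_mask), any(silence_mask))
  sp <- envelope[, speech_mask, drop = FALSE]
  si <- envelope[, silence_mask, drop = FALSE]
  n1 <- ncol(sp); n0 <- ncol(si)
  v1 <- apply(sp, 1L, stats::var)
  v0 <- apply(si, 1L, stats::var)
  pooled <- sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
  d <- (rowMeans(sp) - rowMeans(si)) / pooled
  bad <- !is.finite(d)
  if (any(bad)) {
    warning(sum(bad), " electrode(s) dropped: degenerate pooled SD")
    d[bad] <- NA_real_
  }
  data.frame(cohens_d = d, keep = !is.na(d) & d > threshold)
}
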