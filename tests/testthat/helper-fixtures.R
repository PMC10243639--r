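# Shared fixtures, all built in code at test time.

# a hand-specified tier: 4 phonemes over 2 words, 0.4 s total
toy_tier <- function() {
  phoneme_tier(label = c("P1", "P2", "P3", "P1"),
               start_s = c(0.00, 0.10, 0.20, 0.30),
               end_s = c(0.10, 0.20, 0.30, 0.40),
               word_index = c(1L, 1L, 2L, 2L))
}

# constant-valued spectrogram pair for exact glimpse-ratio arithmetic
const_spec <- function(value, n_frames = 40, n_bands = 100,
                       frame_rate = 100) {
  glimpsetrf:::new_band_spectrogram(
    matrix(value, n_frames, n_bands),
    band_partition(n_bands)$centers, frame_rate)
}

spec_from_matrix <- function(m, frame_rate = 100) {
  glimpsetrf:::new_band_spectrogram(m, band_partition(ncol(m))$centers,
                                    frame_rate)
}

# small random banded-ridge problem with grouped columns
random_ridge_problem <- function(n, p_groups, n_electrodes = 3, seed = 1) {
  set.seed(seed)
  p <- sum(p_groups)
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * n_electrodes), n, n_electrodes)
  lam_group <- 10^runif(length(p_groups), -1, 2)
  lam_col <- rep(lam_group, p_groups)
  list(X = X, Y = Y, lam_col = lam_col, lam_group = lam_group)
}

# independent oracle: direct penalized normal-equation solve
ridge_oracle <- function(X, Y, lam_col) {
  solve(crossprod(X) + diag(lam_col, ncol(X)), crossprod(X, Y))
}
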