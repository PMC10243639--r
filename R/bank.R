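#' Construct a regressor bank
#'
#' A regressor bank is an ordered, named collection of feature groups
#' (matrices sharing one time axis), each of which may carry its own ridge
#' penalty `lambda` and, optionally, a shuffling function defining that
#' group's null (local time shuffle for acoustics, feature-mapping shuffle
#' for phonetics, random-phoneme onsets for words).
#'
#' @param groups named list of time x k numeric matrices.
#' @param frame_rate_hz shared frame rate of the time axis.
#' @param lambdas optional named numeric vector of per-group penalties
#'   (`NA` = not yet tuned/frozen).
#' @param shufflers optional named list of functions `function(seed)` that
#'   return a shuffled version of the group's matrix.
#' @return object of class `regressor_bank`.
#' @export
regressor_bank <- function(groups, frame_rate_hz = 100, lambdas = NULL,
                           shufflers = NULL) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)))
  groups <- lapply(groups, function(g) {
    g <- as.matrix(g)
    if (!all(is.finite(g))) stop("regressor matrices must be finite")
    g
  })
  nt <- unique(vapply(groups, nrow, integer(1)))
  if (length(nt) != 1L) stop("all groups must share the time length")
  lam <- stats::setNames(rep(NA_real_, length(groups)), names(groups))
  if (!is.null(lambdas)) lam[names(lambdas)] <- lambdas
  if (any(!is.na(lam) & lam < 0)) stop("lambdas must be nonnegative")
  structure(
    list(groups = groups, lambdas = lam, shufflers = shufflers,
         frame_rate_hz = frame_rate_hz),
    class = "regressor_bank"
  )
}

#' @export
print.regressor_bank <- function(x, ...) {
  cat(sprintf("<regressor_bank> %d frames @ %g Hz, %d groups:\n",
              nrow(x$groups[[1]]), x$frame_rate_hz, length(x$groups)))
  for (nm in names(x$groups)) {
    cat(sprintf("  %-28s %3d feature(s)  lambda = %s\n", nm,
                ncol(x$groups[[nm]]),
                ifelse(is.na(x$lambdas[nm]), "<untuned>",
                       format(x$lambdas[nm]))))
  }
  invisible(x)
}

#' Drop a group from a bank
#' @param bank a [regressor_bank()].
#' @param name group name to remove.
#' @return the reduced bank.
#' @export
bank_drop <- function(bank, name) {
  if (!name %in% names(bank$groups)) stop("no such group in bank: ", name)
  keep <- setdiff(names(bank$groups), name)
  regressor_bank(bank$groups[keep], bank$frame_rate_hz,
                 bank$lambdas[keep], bank$shufflers[keep])
}

#' Replace a group's matrix (e.g., with a shuffled copy)
#' @param bank a [regressor_bank()].
#' @param name group name.
#' @param matrix replacement matrix of identical shape.
#' @return the modified bank.
#' @export
bank_replace <- function(bank, name, matrix) {
  if (!name %in% names(bank$groups)) stop("no such group in bank: ", name)
  stopifnot(identical(dim(matrix), dim(bank$groups[[name]])))
  bank$groups[[name]] <- matrix
  bank
}

#' Reference per-group ridge penalties for the standard two-talker feature set
#'
#' The regularization strengths established for this paradigm's eight
#' feature groups, usable directly (lambda source `"reference"`) instead of
#' re-tuning. Phonetic-group penalties were originally estimated at a 0 dB
#' glimpse SNR threshold and are frozen across thresholds.
#'
#' @return named numeric vector of length 8.
#' @export
lambda_defaults <- function() {
  c(spectrogram = 42.7,
    glimpsed_edges = 13.5,
    masked_edges = 10.0,
    glimpsed_phoneme_onsets = 31.6,
    masked_phoneme_onsets = 17.8,
    glimpsed_phonetic = 144,
    masked_phonetic = 215,
    word_onsets = 31.6)
}
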