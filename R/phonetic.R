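#' The 22 phonetic feature names
#'
#' Binary articulatory/acoustic attributes used to describe phonemes:
#' voicing, manner, place, and vowel-quality dimensions.
#'
#' @return character vector of length 22.
#' @export
phonetic_feature_names <- function() {
  c("voiced", "unvoiced", "sonorant", "syllabic", "consonantal", "approximant",
    "plosive", "strident", "coronal", "anterior", "dorsal", "front", "back",
    "high", "low", "nasal", "fricative", "obstruent", "bilabial",
    "labiodental", "alveolar", "velar")
}

#' Construct a phoneme-to-feature mapping
#'
#' @param mat binary matrix, phonemes in rows (rownames are phoneme codes),
#'   22 feature columns named as in [phonetic_feature_names()].
#' @return object of class `phonetic_feature_map`.
#' @export
phonetic_feature_map <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (!identical(colnames(mat), phonetic_feature_names())) {
    stop("feature columns must be the 22 standard phonetic features, in order")
  }
  if (!all(mat %in% c(0, 1))) stop("feature vectors must be binary")
  structure(mat, class = c("phonetic_feature_map", "matrix"))
}

#' ARPABET phonetic feature mapping
#'
#' Loads the shipped table mapping the 39 ARPABET phonemes of American
#' English to the 22 binary phonetic features, assembled from standard
#' articulatory phonology.
#'
#' @return a [phonetic_feature_map()] with 39 rows.
#' @export
arpabet_features <- function() {
  path <- system.file("extdata", "arpabet_features.tsv", package = "glimpsetrf")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$phoneme
  phonetic_feature_map(m)
}

#' Per-phoneme glimpse and mask ratios
#'
#' For each phoneme interval, the glimpse ratio is the fraction of
#' time-frequency cells of the fine-band (typically 100-band) spectrogram,
#' within the phoneme's duration, where the talker's energy meets or exceeds
#' the background's scaled by the SNR threshold:
#' `talker >= background * 10^(snr_db / 20)` (magnitude convention; set
#' `convention = "power"` for `10^(snr_db / 10)`). The mask ratio is its
#' complement, so the two always sum to 1 per phoneme.
#'
#' @param talker_spec,background_spec `band_spectrogram`s on a shared time
#'   axis; the background is the competing talker (or the mixture minus the
#'   talker, per the caller's definition).
#' @param tier a [phoneme_tier()].
#' @param snr_threshold_db glimpse SNR threshold in dB (0 = talker must be at
#'   least as loud as the background).
#' @param convention `"magnitude"` (default) or `"power"` dB conversion.
#' @param denominator `"all"` counts every cell of the interval (default);
#'   `"nonzero"` restricts the denominator to cells where the talker has
#'   nonzero energy.
#' @return data frame of class `glimpse_ratios`: one row per phoneme with
#'   `label`, `ratio_glimpse`, `ratio_mask`, and the threshold used.
#' @export
compute_glimpse_ratios <- function(talker_spec, background_spec, tier,
                                   snr_threshold_db = 0,
                                   convention = c("magnitude", "power"),
                                   denominator = c("all", "nonzero")) {
  convention <- match.arg(convention)
  denominator <- match.arg(denominator)
  stopifnot(inherits(talker_spec, "band_spectrogram"),
            inherits(background_spec, "band_spectrogram"),
            is.finite(snr_threshold_db))
  tv <- talker_spec$values
  bv <- background_spec$values
  if (!identical(dim(tv), dim(bv))) {
    stop("talker and background spectrograms must share the time axis")
  }
  rate <- talker_spec$frame_rate_hz
  fac <- 10^(snr_threshold_db / if (convention == "magnitude") 20 else 10)
  ratio <- vapply(seq_len(nrow(tier)), function(i) {
    rows <- interval_frames(tier$start_s[i], tier$end_s[i], rate, nrow(tv))
    g <- tv[rows, , drop = FALSE] >= bv[rows, , drop = FALSE] * fac
    if (denominator == "nonzero") {
      nz <- tv[rows, , drop = FALSE] > 0
      if (!any(nz)) return(0)
      sum(g & nz) / sum(nz)
    } else {
      mean(g)
    }
  }, numeric(1))
  structure(
    data.frame(label = tier$label, ratio_glimpse = ratio,
               ratio_mask = 1 - ratio,
               snr_threshold_db = snr_threshold_db,
               stringsAsFactors = FALSE),
    class = c("glimpse_ratios", "data.frame")
  )
}

#' Glimpsed and masked phonetic-feature regressors
#'
#' Expands a phoneme tier into time-by-feature regressors: within each
#' phoneme's frames, the glimpsed matrix carries `ratio_glimpse` times the
#' phoneme's binary feature vector and the masked matrix carries
#' `ratio_mask` times it, so glimpsed + masked reconstructs the plain binary
#' phonetic matrix exactly. Phoneme-onset regressors are single-frame
#' impulses at each phoneme's start frame scaled by the same ratios.
#'
#' @param tier a [phoneme_tier()].
#' @param fmap a [phonetic_feature_map()] covering every label in the tier.
#' @param ratios a `glimpse_ratios` for the same tier (row-aligned).
#' @param frame_rate_hz frame rate of the output time axis.
#' @param n_frames number of output frames (defaults to the tier duration).
#' @return list with `glimpsed`, `masked` (time x 22), `glimpsed_onsets`,
#'   `masked_onsets` (time x 1).
#' @export
build_phonetic_regressors <- function(tier, fmap, ratios, frame_rate_hz = 100,
                                      n_frames = NULL) {
  stopifnot(inherits(fmap, "phonetic_feature_map"),
            nrow(ratios) == nrow(tier))
  unknown <- setdiff(unique(tier$label), rownames(fmap))
  if (length(unknown)) {
    stop("phoneme label(s) missing from feature map: ",
         paste(unknown, collapse = ", "))
  }
  n_frames <- n_frames %||%
    frame_count(attr(tier, "total_duration_s"), frame_rate_hz)
  nf <- ncol(fmap)
  gl <- matrix(0, n_frames, nf, dimnames = list(NULL, colnames(fmap)))
  ma <- gl
  gon <- matrix(0, n_frames, 1L, dimnames = list(NULL, "phoneme_onset"))
  mon <- gon
  for (i in seq_len(nrow(tier))) {
    rows <- interval_frames(tier$start_s[i], tier$end_s[i], frame_rate_hz,
                            n_frames)
    fv <- fmap[tier$label[i], ]
    rg <- ratios$ratio_glimpse[i]
    gl[rows, ] <- rep(rg * fv, each = length(rows))
    ma[rows, ] <- rep((1 - rg) * fv, each = length(rows))
    gon[rows[1L], 1L] <- rg
    mon[rows[1L], 1L] <- 1 - rg
  }
  list(glimpsed = gl, masked = ma, glimpsed_onsets = gon, masked_onsets = mon)
}

#' Word-onset impulse regressor
#'
#' A binary impulse at the start frame of the first phoneme of each word.
#'
#' @param tier a [phoneme_tier()].
#' @param frame_rate_hz frame rate of the output time axis.
#' @param n_frames number of output frames (defaults to the tier duration).
#' @return time x 1 matrix with exactly one 1 per word.
#' @export
word_onset_regressor <- function(tier, frame_rate_hz = 100, n_frames = NULL) {
  n_frames <- n_frames %||%
    frame_count(attr(tier, "total_duration_s"), frame_rate_hz)
  out <- matrix(0, n_frames, 1L, dimnames = list(NULL, "word_onset"))
  first <- !duplicated(tier$word_index)
  for (i in which(first)) {
    rows <- interval_frames(tier$start_s[i], tier$end_s[i], frame_rate_hz,
                            n_frames)
    out[rows[1L], 1L] <- 1
  }
  out
}

#' Shuffle the phoneme-to-feature mapping
#'
#' Permutes the feature vectors over phoneme labels: each phoneme is
#' consistently mapped to one (generally wrong) vector, the multiset of
#' vectors is preserved, and articulatory information is destroyed while
#' phoneme identity and timing are retained.
#'
#' @param fmap a [phonetic_feature_map()].
#' @param seed integer seed; same seed, same permutation.
#' @return a shuffled [phonetic_feature_map()].
#' @export
shuffle_feature_mapping <- function(fmap, seed = NULL) {
  stopifnot(inherits(fmap, "phonetic_feature_map"), nrow(fmap) >= 2L)
  perm <- with_seed(seed, sample.int(nrow(fmap)))
  out <- unclass(fmap)[perm, , drop = FALSE]
  rownames(out) <- rownames(fmap)
  phonetic_feature_map(out)
}

#' Shuffled word-onset regressor
#'
#' Places one impulse per word at the onset of a uniformly chosen phoneme
#' within that word (the matched null for word-initial onsets: same count
#' per word, same phoneme-onset timing statistics).
#'
#' @inheritParams word_onset_regressor
#' @param seed integer seed.
#' @return time x 1 matrix with exactly one 1 per word, at a phoneme onset.
#' @export
shuffle_word_onsets <- function(tier, frame_rate_hz = 100, n_frames = NULL,
                                seed = NULL) {
  n_frames <- n_frames %||%
    frame_count(attr(tier, "total_duration_s"), frame_rate_hz)
  out <- matrix(0, n_frames, 1L, dimnames = list(NULL, "word_onset_shuffled"))
  idx_by_word <- split(seq_len(nrow(tier)), tier$word_index)
  picks <- with_seed(seed, {
    vapply(idx_by_word, function(ix) ix[sample.int(length(ix), 1L)],
           integer(1))
  })
  for (i in picks) {
    rows <- interval_frames(tier$start_s[i], tier$end_s[i], frame_rate_hz,
                            n_frames)
    out[rows[1L], 1L] <- 1
  }
  out
}
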