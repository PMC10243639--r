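#' Construct a phoneme tier
#'
#' A phoneme tier is the forced-alignment view of an utterance: one row per
#' phoneme interval with its label, start/end times in seconds, and the index
#' of the word it belongs to. Intervals must be sorted, non-overlapping, and
#' strictly positive in duration; word indices must be non-decreasing.
#'
#' @param label character phoneme codes (e.g., ARPABET).
#' @param start_s,end_s interval boundaries in seconds.
#' @param word_index integer word membership, non-decreasing.
#' @return a data frame of class `phoneme_tier` with attribute
#'   `total_duration_s` (the last interval's end).
#' @export
phoneme_tier <- function(label, start_s, end_s, word_index) {
  stopifnot(length(label) == length(start_s),
            length(start_s) == length(end_s),
            length(end_s) == length(word_index))
  if (any(end_s <= start_s)) stop("phoneme intervals must have end > start")
  if (length(start_s) > 1L) {
    if (is.unsorted(start_s)) stop("phoneme intervals must be sorted")
    if (any(start_s[-1] < end_s[-length(end_s)] - 1e-9)) {
      stop("phoneme intervals must not overlap")
    }
    if (is.unsorted(word_index)) stop("word_index must be non-decreasing")
  }
  out <- data.frame(label = as.character(label), start_s = start_s,
                    end_s = end_s, word_index = as.integer(word_index),
                    stringsAsFactors = FALSE)
  attr(out, "total_duration_s") <- max(end_s)
  class(out) <- c("phoneme_tier", "data.frame")
  out
}

#' Read a phoneme alignment from a tab-separated file
#'
#' Expects four columns, `label`, `start_s`, `end_s`, `word_index`, with or
#' without a header line. Intervals labelled `sil`, `sp`, or empty are
#' dropped (silence/pause markers from forced aligners).
#'
#' @param path file path.
#' @return a [phoneme_tier()].
#' @export
read_alignment_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("label", first, fixed = TRUE)
  df <- if (header) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      col.names = c("label", "start_s", "end_s", "word_index"))
  }
  keep <- !(df$label %in% c("", "sil", "sp", "SIL", "SP"))
  df <- df[keep, , drop = FALSE]
  phoneme_tier(df$label, df$start_s, df$end_s, df$word_index)
}

#' Read an interval tier from a Praat TextGrid
#'
#' Minimal parser for long-format TextGrid files: extracts one named
#' IntervalTier and returns its non-empty intervals. Word membership is
#' taken from a parallel word tier if `word_tier` is given (each phoneme is
#' assigned to the word interval containing its midpoint); otherwise every
#' phoneme is its own word.
#'
#' @param path TextGrid file path.
#' @param tier name of the phoneme IntervalTier (default `"phones"`).
#' @param word_tier optional name of a word IntervalTier.
#' @return a [phoneme_tier()].
#' @export
read_textgrid <- function(path, tier = "phones", word_tier = NULL) {
  lines <- readLines(path, warn = FALSE)
  parse_tier <- function(name) {
    nm <- grep(sprintf('name\\s*=\\s*"%s"', name), lines)
    if (length(nm) == 0L) stop("tier not found in TextGrid: ", name)
    ends <- grep('name\\s*=\\s*"', lines)
    stop_at <- c(ends[ends > nm[1]], length(lines) + 1L)[1]
    block <- lines[nm[1]:(stop_at - 1L)]
    num <- function(pat) as.numeric(sub(paste0(".*", pat, "\\s*=\\s*"), "",
                                        grep(pat, block, value = TRUE)))
    txt <- sub('.*text\\s*=\\s*"(.*)".*', "\\1",
               grep("text\\s*=", block, value = TRUE))
    data.frame(start_s = num("xmin")[-1], end_s = num("xmax")[-1],
               label = txt, stringsAsFactors = FALSE)
  }
  ph <- parse_tier(tier)
  ph <- ph[!(ph$label %in% c("", "sil", "sp", "SIL", "SP")), , drop = FALSE]
  if (!is.null(word_tier)) {
    wd <- parse_tier(word_tier)
    wd <- wd[wd$label != "", , drop = FALSE]
    mid <- (ph$start_s + ph$end_s) / 2
    widx <- findInterval(mid, wd$start_s)
    widx[widx < 1L] <- 1L
  } else {
    widx <- seq_len(nrow(ph))
  }
  phoneme_tier(ph$label, ph$start_s, ph$end_s, widx)
}

# frames owned by an interval: [round(start*rate), round(end*rate)) half-open,
# returned 1-based; errors on empty quantized intervals
interval_frames <- function(start_s, end_s, frame_rate_hz, n_frames) {
  a <- as.integer(round(start_s * frame_rate_hz))
  b <- as.integer(round(end_s * frame_rate_hz))
  if (b <= a) stop(sprintf("interval [%g, %g] s empty after frame quantization",
                           start_s, end_s))
  if (a < 0L || b > n_frames) {
    stop(sprintf("interval [%g, %g] s outside the spectrogram time range",
                 start_s, end_s))
  }
  (a + 1L):b
}
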