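# Minimal RIFF/WAVE I/O for mono PCM-16 and IEEE float-32 files. Covers the
# formats forced-alignment workflows actually emit; anything fancier
# (compressed codecs, >2 channels) is out of scope.

#' Read a mono WAV file
#'
#' Supports uncompressed PCM (8/16/32-bit integer) and 32-bit IEEE float
#' data. Multi-channel files are averaged down to mono.
#'
#' @param path file path.
#' @return list with `samples` (numeric in `[-1, 1]` for integer PCM) and
#'   `fs` (sampling rate in Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk in ", path)
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1L, 2L, endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1L, 2L, endian = "little"),
        fs = readBin(raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1L, 2L, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      bytes <- fmt$bits / 8L
      n <- sz %/% bytes
      if (fmt$audio_format == 3L && fmt$bits == 32L) {
        x <- readBin(con, "numeric", n, 4L, endian = "little")
      } else if (fmt$audio_format == 1L) {
        x <- readBin(con, "integer", n, bytes, signed = bytes > 1L,
                     endian = "little")
        x <- x / 2^(fmt$bits - 1)
        if (bytes == 1L) x <- (x - 1) # 8-bit PCM is unsigned
      } else {
        stop("unsupported WAV encoding (format tag ", fmt$audio_format, ")")
      }
      if (fmt$n_channels > 1L) {
        x <- colMeans(matrix(x, nrow = fmt$n_channels))
      }
      return(list(samples = as.numeric(x), fs = fmt$fs))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
  }
}

#' Write a mono WAV file (PCM 16-bit)
#'
#' @param samples numeric vector; values are clipped to `[-1, 1]`.
#' @param fs sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path) {
  x <- pmax(pmin(samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_sz <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")   # PCM
  writeBin(1L, con, 2L, endian = "little")   # mono
  writeBin(as.integer(fs), con, 4L, endian = "little")
  writeBin(as.integer(fs * 2L), con, 4L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}
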