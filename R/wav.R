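#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for the formats this package writes and consumes:
#' PCM 16-bit and IEEE float 32-bit, single channel. Samples are returned in
#' full-scale units on \[-1, 1\] (16-bit PCM is divided by 32768, the dBFS
#' reference for integer audio).
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector in \[-1, 1\]) and `rate` (Hz).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little") # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, size = 2, endian = "little"),
        n_channels   = readBin(raw[3:4], "integer", 1, size = 2, endian = "little"),
        rate         = readBin(raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, size = 2, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt")
      if (fmt$n_channels != 1L) stop("only mono WAV supported")
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        x <- readBin(con, "integer", sz / 2, size = 2, signed = TRUE,
                     endian = "little")
        samples <- x / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "double", sz / 4, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (need PCM16 or float32)")
      }
    } else {
      readBin(con, "raw", sz + sz %% 2) # skip unknown chunk (word aligned)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk in ", path)
  list(samples = samples, rate = fmt$rate)
}

#' Write a mono WAV file
#'
#' @param samples Numeric vector in full-scale units \[-1, 1\]; values outside
#'   are clipped.
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @param bits Either 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, bits = 16L) {
  stopifnot(is.numeric(samples), length(samples) > 0, rate > 0)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  if (bits == 16L) {
    data_sz <- 2L * n; fmt_code <- 1L; block <- 2L
  } else if (bits == 32L) {
    data_sz <- 4L * n; fmt_code <- 3L; block <- 4L
  } else stop("bits must be 16 or 32")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(fmt_code), con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  x <- pmin(1, pmax(-1, samples))
  if (bits == 16L) {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.double(x), con, size = 4, endian = "little")
  }
  invisible(path)
}
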