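#' Write a mono WAV file
#'
#' Minimal RIFF/WAVE writer for single-channel recordings: 16-bit PCM
#' (samples clipped to \[-1, 1\] and rounded) or 32-bit IEEE float.  Output
#' bytes are a pure function of the samples, so seeded synthetic recordings
#' are bit-identical across runs.
#'
#' @param samples Numeric vector of samples (pressure in Pa or normalised
#'   amplitude; stored as given for float, scaled by 32767 for PCM16).
#' @param path Output file path.
#' @param rate Sampling rate, Hz.  Default 44100.
#' @param format `"float32"` (default, lossless for analysis pipelines) or
#'   `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, rate = 44100,
                      format = c("float32", "pcm16")) {
  format <- match.arg(format)
  stopifnot(is.numeric(samples), length(samples) > 0L, rate > 0)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop_invalid("WAV samples must be finite")
  bits <- if (format == "pcm16") 16L else 32L
  fmt_code <- if (format == "pcm16") 1L else 3L
  block_align <- bits %/% 8L
  data_bytes <- length(samples) * block_align
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * block_align), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    x <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
    writeBin(x, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports the subset written by [write_wav()] plus common PCM variants:
#' mono, 16- or 24-bit integer PCM and 32-bit IEEE float.  Unknown chunks
#' are skipped.
#'
#' @param path File path.
#' @return A list with `samples` (numeric, integer formats scaled to
#'   \[-1, 1\]) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF"))
    stop_invalid("'%s' is not a RIFF file", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE"))
    stop_invalid("'%s' is not a WAVE file", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4L)
      stop_invalid("'%s': no data chunk found", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, integer(), size = 2, endian = "little"),
        channels = readBin(con, integer(), size = 2, endian = "little"),
        rate = readBin(con, integer(), size = 4, endian = "little"),
        byte_rate = readBin(con, integer(), size = 4, endian = "little"),
        block_align = readBin(con, integer(), size = 2, endian = "little"),
        bits = readBin(con, integer(), size = 2, endian = "little"))
      if (size > 16L) readBin(con, raw(), n = size - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stop_invalid("'%s': data chunk before fmt", path)
      if (fmt$channels != 1L)
        stop_invalid("'%s': only mono WAV is supported (found %d channels)",
                     path, fmt$channels)
      n <- size %/% (fmt$bits %/% 8L)
      samples <- if (fmt$code == 3L && fmt$bits == 32L) {
        readBin(con, numeric(), n = n, size = 4, endian = "little")
      } else if (fmt$code == 1L && fmt$bits == 16L) {
        readBin(con, integer(), n = n, size = 2, endian = "little",
                signed = TRUE) / 32767
      } else if (fmt$code == 1L && fmt$bits == 24L) {
        b <- readBin(con, integer(), n = 3L * n, size = 1, signed = FALSE)
        b <- matrix(b, nrow = 3L)
        v <- b[1L, ] + 256 * b[2L, ] + 65536 * b[3L, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388607
      } else {
        stop_invalid("'%s': unsupported WAV format (code %d, %d bit)", path,
                     fmt$code, fmt$bits)
      }
      return(list(samples = samples, rate = fmt$rate))
    } else {
      readBin(con, raw(), n = size + size %% 2L)
    }
  }
}
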