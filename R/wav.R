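#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader covering the formats heart-sound recorders
#' produce: PCM 8/16/24/32-bit integer and IEEE float32/float64, mono or
#' stereo. Samples are returned as doubles scaled to [-1, 1].
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric matrix, one column per channel),
#'   `sample_rate` (Hz) and `channels`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        channels     = readBin(body[3:4], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        sample_rate  = readBin(body[5:8], "integer", 1, size = 4,
                               endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, size = 2,
                               endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk: ", path)
  if (fmt$audio_format == 0xFFFE) fmt$audio_format <- 1L  # extensible: assume PCM

  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  x <- if (fmt$audio_format == 3L) {
    readBin(data_raw, "double", n, size = bytes, endian = "little")
  } else if (fmt$bits == 8L) {
    (readBin(data_raw, "integer", n, size = 1, signed = FALSE) - 128) / 128
  } else if (fmt$bits == 16L) {
    readBin(data_raw, "integer", n, size = 2, endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    ifelse(v >= 8388608, v - 16777216, v) / 8388608
  } else if (fmt$bits == 32L) {
    readBin(data_raw, "integer", n, size = 4, endian = "little") / 2147483648
  } else stop("unsupported bit depth: ", fmt$bits)

  samples <- matrix(x, ncol = fmt$channels, byrow = TRUE)
  list(samples = samples, sample_rate = fmt$sample_rate,
       channels = fmt$channels)
}

#' Write a WAV file (16-bit PCM)
#'
#' @param samples Numeric vector (mono) or matrix with one column per
#'   channel, amplitudes in [-1, 1]; values outside are clipped.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  channels <- ncol(samples)
  x <- as.vector(t(samples))            # interleave channels
  x <- pmax(-1, pmin(1, x))
  ints <- as.integer(round(x * 32767))
  n_bytes <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(channels, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * channels * 2L), con, size = 4,
           endian = "little")
  writeBin(as.integer(channels * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}
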