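#' Construct a waveform
#'
#' A `waveform` is the carrier object for all acoustic measures: a mono
#' sampled signal with its sampling rate and an optional time origin.
#' Amplitudes are dimensionless linear units, nominally full scale in
#' `[-1, 1]` when read from or written to PCM WAV.
#'
#' @param samples numeric vector of sample amplitudes (length >= 1).
#' @param rate sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds (default 0).
#' @return An object of class `waveform` with fields `samples`, `rate`, `t0`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * (0:15999) / 16000), rate = 16000)
#' duration_s(w)
#' @export
waveform <- function(samples, rate, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("waveform must contain at least one sample")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("sampling rate must be a single positive number")
  structure(list(samples = samples, rate = as.numeric(rate), t0 = as.numeric(t0)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz, %.3f s>\n",
              length(x$samples), x$rate, duration_s(x)))
  invisible(x)
}

#' Duration of a waveform in seconds
#'
#' @param w a [waveform()].
#' @return Duration in seconds, `n_samples / rate`.
#' @export
duration_s <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$rate
}

#' Read a mono PCM WAV file
#'
#' Reads 8-, 16-, 24- or 32-bit integer PCM and 32-/64-bit IEEE float WAV.
#' Integer samples are rescaled to full-scale `[-1, 1]`. Multichannel files
#' are rejected: all downstream acoustics assume a single channel.
#'
#' @param path path to a WAV file.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found in ", path)
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        rate         = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$n_channels != 1L)
        stop("multichannel WAV not supported (", fmt$n_channels,
             " channels); supply mono audio")
      bytes_per <- fmt$bits / 8
      n <- sz %/% bytes_per
      x <- if (fmt$audio_format == 3L) {
        readBin(con, "double", n, bytes_per, endian = "little")
      } else if (fmt$bits == 8L) {
        (readBin(con, "integer", n, 1, signed = FALSE) - 128) / 128
      } else if (fmt$bits == 16L) {
        readBin(con, "integer", n, 2, endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        raw3 <- readBin(con, "raw", n * 3)
        b <- matrix(as.integer(raw3), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        ifelse(v >= 8388608, v - 16777216, v) / 8388608
      } else if (fmt$bits == 32L) {
        readBin(con, "integer", n, 4, endian = "little") / 2147483648
      } else stop("unsupported PCM bit depth: ", fmt$bits)
      return(waveform(x, rate = fmt$rate))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
}

#' Write a waveform to a 16-bit PCM mono WAV file
#'
#' Samples are clipped to `[-1, 1]` before quantization.
#'
#' @param w a [waveform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmin(1, pmax(-1, w$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(1), con, 2, endian = "little")      # PCM
  writeBin(as.integer(1), con, 2, endian = "little")      # mono
  writeBin(as.integer(round(w$rate)), con, 4, endian = "little")
  writeBin(as.integer(round(w$rate) * 2), con, 4, endian = "little")
  writeBin(as.integer(2), con, 2, endian = "little")
  writeBin(as.integer(16), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
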