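#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for PCM audio. 16-bit PCM is the native format of
#' the corpus this package targets; 8-bit and 32-bit integer PCM and 32-bit
#' IEEE float are converted on read. Multi-channel files are mixed down to
#' mono by averaging channels.
#'
#' @param path Path to a `.wav` file.
#' @return A waveform object: `list(samples, sample_rate)` of class
#'   `"waveform"`, samples in `[-1, 1]`.
#' @seealso [write_wav()], [waveform()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort(paste0("not a RIFF file: ", path))
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort(paste0("not a WAVE file: ", path))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort(paste0("missing fmt/data chunk: ", path))

  x <- switch(
    as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                   signed = TRUE, endian = "little") / 32768,
    "8"  = (readBin(data_raw, "integer", length(data_raw), 1,
                    signed = FALSE) - 128) / 128,
    "32" = if (fmt$audio_format == 3) {
      readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
    } else {
      readBin(data_raw, "integer", length(data_raw) / 4, 4, endian = "little") / 2147483648
    },
    abort(paste0("unsupported bit depth: ", fmt$bits))
  )
  if (fmt$n_channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  waveform(x, fmt$sample_rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param wav A [waveform()] object (or numeric vector with `sample_rate`).
#' @param path Output path.
#' @param sample_rate Sample rate in Hz; taken from `wav` if it is a waveform.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wav, path, sample_rate = NULL) {
  if (inherits(wav, "waveform")) {
    sample_rate <- wav$sample_rate
    x <- wav$samples
  } else {
    x <- as.numeric(wav)
    if (is.null(sample_rate)) abort("sample_rate required for a bare numeric vector")
  }
  x <- pmax(pmin(x, 1), -1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Construct a waveform
#'
#' The raw-audio container used by both feature branches: mono samples in
#' `[-1, 1]` plus a sample rate. Feature extractors expect 48 kHz audio;
#' [resample_wav()] converts other rates.
#'
#' @param samples Numeric vector of amplitudes.
#' @param sample_rate Positive integer, Hz.
#' @return An object of class `"waveform"`.
#' @export
waveform <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), length(samples) > 0,
            is.numeric(sample_rate), sample_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.integer(sample_rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %d Hz (%.2f s)>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Resample a waveform by linear interpolation
#'
#' @param wav A [waveform()].
#' @param sample_rate Target rate in Hz.
#' @return A [waveform()] at `sample_rate`.
#' @export
resample_wav <- function(wav, sample_rate = 48000L) {
  if (wav$sample_rate == sample_rate) return(wav)
  n_out <- max(1L, round(length(wav$samples) * sample_rate / wav$sample_rate))
  t_in <- seq(0, 1, length.out = length(wav$samples))
  t_out <- seq(0, 1, length.out = n_out)
  waveform(approx(t_in, wav$samples, xout = t_out)$y, sample_rate)
}
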