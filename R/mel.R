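#' @keywords internal
#' Slice a signal into overlapping frames (columns), no padding.
#' T = 1 + floor((len - win) / hop) frames.
frame_signal <- function(x, win, hop) {
  n <- length(x)
  if (n < win) abort(sprintf("signal too short: %d samples < one %d-sample window", n, win))
  n_frames <- 1L + (n - win) %/% hop
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(win), starts, `+`)
  matrix(x[idx], nrow = win)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank (HTK mel scale)
#'
#' @param n_mels Number of triangular filters.
#' @param n_fft FFT length.
#' @param sample_rate Sample rate in Hz.
#' @param fmin,fmax Band edges in Hz (`fmax = NULL` means Nyquist).
#' @return `n_fft/2 + 1` x `n_mels` matrix of filter weights.
#' @keywords internal
mel_filterbank <- function(n_mels, n_fft, sample_rate, fmin = 0, fmax = NULL) {
  if (is.null(fmax)) fmax <- sample_rate / 2
  n_bins <- n_fft %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1L) * sample_rate / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L))
  fb <- matrix(0, n_bins, n_mels)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ctr <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (bin_hz - lo) / (ctr - lo)
    down <- (hi - bin_hz) / (hi - ctr)
    fb[, m] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Log-mel spectrogram
#'
#' Short-time analysis with a Hamming window (25 ms window, 10 ms hop by
#' default), an FFT sized to the next power of two above the window, a
#' 64-band triangular mel filterbank on the HTK mel scale, and log
#' compression `log(energy + 1e-10)`.
#'
#' @param wav A [waveform()].
#' @param n_mels Number of mel bands (default 64).
#' @param win_ms Window length in milliseconds (default 25).
#' @param hop_ms Hop in milliseconds (default 10).
#' @return T x `n_mels` matrix of log mel energies, one row per frame,
#'   `T = 1 + floor((len - win)/hop)`.
#' @examples
#' wav <- waveform(sin(2 * pi * 1000 * seq(0, 1, by = 1 / 48000)), 48000)
#' m <- compute_mel_spectrogram(wav)
#' dim(m)
#' @export
compute_mel_spectrogram <- function(wav, n_mels = 64L, win_ms = 25, hop_ms = 10) {
  stopifnot(inherits(wav, "waveform"))
  fs <- wav$sample_rate
  win <- round(fs * win_ms / 1000)
  hop <- round(fs * hop_ms / 1000)
  frames <- frame_signal(wav$samples, win, hop)
  n_fft <- 2^ceiling(log2(win))
  w <- hamming_window(win)
  padded <- matrix(0, n_fft, ncol(frames))
  padded[seq_len(win), ] <- frames * w
  spec <- mvfft(padded)[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
  power <- Mod(spec)^2
  fb <- mel_filterbank(n_mels, n_fft, fs)
  t(log(crossprod(fb, power) + 1e-10))
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

#' Regression delta of a framewise feature matrix
#'
#' HTK-convention delta: a least-squares slope over a symmetric window of
#' `width` frames on each side, `d_t = sum_n n (x_{t+n} - x_{t-n}) / (2 sum
#' n^2)`, with edge frames handled by replication padding. `order = 2`
#' applies the operator twice.
#'
#' @param feature_matrix T x K matrix, rows are frames.
#' @param order 1 (delta) or 2 (delta-delta).
#' @param width Half-window in frames (default 2).
#' @return Matrix of the same shape.
#' @export
compute_delta <- function(feature_matrix, order = 1L, width = 2L) {
  x <- as.matrix(feature_matrix)
  if (nrow(x) == 0 || ncol(x) == 0) abort("empty feature matrix")
  stopifnot(order %in% c(1L, 2L))
  d <- delta_once(x, width)
  if (order == 2L) d <- delta_once(d, width)
  d
}

delta_once <- function(x, width) {
  n <- nrow(x)
  pad_top <- x[rep(1L, width), , drop = FALSE]
  pad_bot <- x[rep(n, width), , drop = FALSE]
  xp <- rbind(pad_top, x, pad_bot)
  denom <- 2 * sum(seq_len(width)^2)
  d <- matrix(0, n, ncol(x))
  for (k in seq_len(width)) {
    d <- d + k * (xp[(width + k + 1L):(width + k + n), , drop = FALSE] -
                  xp[(width - k + 1L):(width - k + n), , drop = FALSE])
  }
  d / denom
}

#' Bilinear resize of a matrix
#'
#' Deterministic bilinear interpolation on the pixel-center grid, used to
#' bring variable-length spectrograms to the fixed square input size of the
#' convolutional network.
#'
#' @param x Numeric matrix.
#' @param out_rows,out_cols Target size.
#' @return `out_rows` x `out_cols` matrix.
#' @export
resize_bilinear <- function(x, out_rows, out_cols) {
  x <- as.matrix(x)
  ri <- interp_axis(nrow(x), out_rows)
  ci <- interp_axis(ncol(x), out_cols)
  top <- x[ri$lo, ci$lo, drop = FALSE] * ((1 - ri$w) %o% (1 - ci$w)) +
         x[ri$lo, ci$hi, drop = FALSE] * ((1 - ri$w) %o% ci$w)
  bot <- x[ri$hi, ci$lo, drop = FALSE] * (ri$w %o% (1 - ci$w)) +
         x[ri$hi, ci$hi, drop = FALSE] * (ri$w %o% ci$w)
  top + bot
}

interp_axis <- function(n_in, n_out) {
  # align pixel centers: source position of output pixel i
  pos <- if (n_out == 1L) 0 else (seq_len(n_out) - 1L) * (n_in - 1L) / (n_out - 1L)
  lo <- pmin(floor(pos) + 1L, n_in)
  hi <- pmin(lo + 1L, n_in)
  w <- pos - (lo - 1L)
  list(lo = lo, hi = hi, w = w)
}

#' Three-channel mel-spectrum image
#'
#' Stacks the log-mel spectrogram with its first- and second-order regression
#' deltas (computed at native frame resolution, before resizing) and resizes
#' each channel to a square `size` x `size` image. The result is the input of
#' the student/teacher convolutional network.
#'
#' @param wav A [waveform()].
#' @param size Output side length (default 256; use 64 for the desk scale).
#' @param n_mels,win_ms,hop_ms Passed to [compute_mel_spectrogram()].
#' @return `size` x `size` x 3 array: channel 1 log-mel, channel 2 delta,
#'   channel 3 delta-delta.
#' @export
build_melspec3d <- function(wav, size = 256L, n_mels = 64L, win_ms = 25, hop_ms = 10) {
  m <- compute_mel_spectrogram(wav, n_mels = n_mels, win_ms = win_ms, hop_ms = hop_ms)
  d1 <- compute_delta(m, 1L)
  d2 <- compute_delta(m, 2L)
  out <- array(0, c(size, size, 3L))
  out[, , 1L] <- resize_bilinear(m, size, size)
  out[, , 2L] <- resize_bilinear(d1, size, size)
  out[, , 3L] <- resize_bilinear(d2, size, size)
  out
}
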