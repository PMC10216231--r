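#' Frame-level low-level descriptors
#'
#' Computes the 16 per-frame descriptors of the Interspeech-2009 emotion
#' challenge feature set on 25 ms frames with a 10 ms hop:
#' zero-crossing rate, RMS frame energy, pitch (autocorrelation estimate,
#' normalized to 500 Hz, 0 on unvoiced frames), harmonics-to-noise ratio
#' from the autocorrelation function (dB, clamped to \[-60, 60\]), and
#' HTK-style MFCC 1-12 (pre-emphasis 0.97, 26 HTK-mel bands over 0-8 kHz,
#' DCT-II, cepstral liftering 22).
#'
#' @param wav A [waveform()]; resampled to 48 kHz if at another rate.
#' @param win_ms,hop_ms Frame length and hop in milliseconds.
#' @param f0_min,f0_max Pitch search range in Hz.
#' @param voicing_threshold Minimum autocorrelation peak (relative to lag-0)
#'   for a frame to count as voiced.
#' @return T x 16 matrix with columns
#'   `zcr, rms, f0, hnr, mfcc1..mfcc12` (`f0` already divided by 500 Hz).
#' @export
extract_llds <- function(wav, win_ms = 25, hop_ms = 10,
                         f0_min = 50, f0_max = 500,
                         voicing_threshold = 0.3) {
  stopifnot(inherits(wav, "waveform"))
  wav <- resample_wav(wav, 48000L)
  fs <- wav$sample_rate
  x <- wav$samples
  win <- round(fs * win_ms / 1000)
  hop <- round(fs * hop_ms / 1000)
  frames <- frame_signal(x, win, hop)
  n_frames <- ncol(frames)

  ## --- time-signal descriptors -------------------------------------------
  sgn <- sign(frames)
  sgn[sgn == 0] <- 1           # zeros treated as positive: no spurious crossings
  zcr <- colMeans(abs(diff(sgn)) > 0)
  rms <- sqrt(colMeans(frames^2))

  ## --- autocorrelation pitch + HNR ---------------------------------------
  lag_min <- max(2L, floor(fs / f0_max))
  lag_max <- min(win - 1L, ceiling(fs / f0_min))
  n_fft <- 2^ceiling(log2(2L * win))
  padded <- matrix(0, n_fft, n_frames)
  padded[seq_len(win), ] <- frames
  spec_pow <- Mod(mvfft(padded))^2
  r <- Re(mvfft(spec_pow, inverse = TRUE)) / n_fft
  r0 <- r[1L, ]
  r_band <- r[(lag_min + 1L):(lag_max + 1L), , drop = FALSE]
  peak_rel <- max.col(t(r_band), ties.method = "first")
  peak_val <- r_band[cbind(peak_rel, seq_len(n_frames))]
  lag <- lag_min + peak_rel - 1L
  voiced <- r0 > 0 & peak_val / pmax(r0, .Machine$double.eps) > voicing_threshold
  f0 <- ifelse(voiced, (fs / lag) / 500, 0)
  f0 <- pmin(pmax(f0, 0), 1)
  hnr <- rep(-60, n_frames)
  ok <- r0 > 0 & peak_val > 0
  ratio <- peak_val[ok] / pmax(r0[ok] - peak_val[ok], .Machine$double.eps)
  hnr[ok] <- 10 * log10(ratio)
  hnr <- pmin(pmax(hnr, -60), 60)

  ## --- HTK-style MFCC 1-12 -----------------------------------------------
  mfcc <- htk_mfcc(x, fs, win, hop, n_frames)

  out <- cbind(zcr, rms, f0, hnr, mfcc)
  colnames(out) <- c("zcr", "rms", "f0", "hnr", paste0("mfcc", 1:12))
  out
}

#' @keywords internal
htk_mfcc <- function(x, fs, win, hop, n_frames,
                     n_bands = 26L, n_ceps = 12L, lifter = 22L,
                     fmin = 0, fmax = 8000, preemph = 0.97) {
  xe <- x - preemph * c(0, x[-length(x)])   # xe[t] = x[t] - 0.97 x[t-1]
  frames <- frame_signal(xe, win, hop)[, seq_len(n_frames), drop = FALSE]
  n_fft <- 2^ceiling(log2(win))
  w <- hamming_window(win)
  padded <- matrix(0, n_fft, ncol(frames))
  padded[seq_len(win), ] <- frames * w
  mag <- Mod(mvfft(padded))[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
  fb <- mel_filterbank(n_bands, n_fft, fs, fmin = fmin, fmax = fmax)
  fbe <- log(pmax(crossprod(fb, mag), 1e-10))          # n_bands x T
  j <- seq_len(n_bands)
  dct <- sqrt(2 / n_bands) *
    outer(seq_len(n_ceps), j, function(i, j) cos(pi * i * (j - 0.5) / n_bands))
  cep <- dct %*% fbe                                   # n_ceps x T
  lift <- 1 + (lifter / 2) * sin(pi * seq_len(n_ceps) / lifter)
  t(cep * lift)
}
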