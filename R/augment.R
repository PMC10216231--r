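#' Augmentation configuration
#'
#' Three perturbations feed the semi-supervised wiring: `eta` (horizontal
#' flip of the time axis plus a random crop after edge-replication padding,
#' applied to every spectrogram input), `eta'` (Gaussian noise on unlabeled
#' spectrograms entering the student), and `eta''` (Gaussian noise on
#' unlabeled IS09 vectors entering the AE). The noise amplitude 0.3 is
#' expressed in units of the tensor's robust scale (IQR / 1.349), so the
#' same number is meaningful for spectrograms and feature vectors.
#'
#' @param flip_prob Probability of a time-axis flip (default 0.5).
#' @param crop_pad Padding in pixels before the random crop (default 8;
#'   scaled down proportionally for small inputs).
#' @param noise_amplitude Noise SD in robust-scale units (default 0.3).
#' @return A list of class `"augment_config"`.
#' @export
augment_config <- function(flip_prob = 0.5, crop_pad = 8L, noise_amplitude = 0.3) {
  stopifnot(flip_prob >= 0, flip_prob <= 1, crop_pad >= 0, noise_amplitude >= 0)
  structure(list(flip_prob = flip_prob, crop_pad = as.integer(crop_pad),
                 noise_amplitude = noise_amplitude),
            class = "augment_config")
}

#' Flip-and-crop spectrogram augmentation (eta)
#'
#' With probability `flip_prob` reverses the time axis (rows) of all three
#' channels, then pads by `crop_pad` pixels with edge replication and takes
#' a random crop back to the original size. Draws from the current RNG
#' stream.
#'
#' @param x `H x H x 3` mel-spectrum array.
#' @param cfg An [augment_config()].
#' @param force_flip Force the flip regardless of `flip_prob` (used to test
#'   the involution property).
#' @return Array of the same shape.
#' @export
flip_crop <- function(x, cfg = augment_config(), force_flip = FALSE) {
  d <- dim(x)
  if (force_flip || (cfg$flip_prob > 0 && runif(1) < cfg$flip_prob)) {
    x <- x[d[1L]:1L, , , drop = FALSE]
  }
  p <- cfg$crop_pad
  if (p > 0L) {
    ri <- pmin(pmax(seq_len(d[1L] + 2L * p) - p, 1L), d[1L])
    ci <- pmin(pmax(seq_len(d[2L] + 2L * p) - p, 1L), d[2L])
    xp <- x[ri, ci, , drop = FALSE]
    oi <- sample.int(2L * p + 1L, 1L) - 1L
    oj <- sample.int(2L * p + 1L, 1L) - 1L
    x <- xp[oi + seq_len(d[1L]), oj + seq_len(d[2L]), , drop = FALSE]
  }
  x
}

#' Additive Gaussian noise augmentation (eta' / eta'')
#'
#' Adds i.i.d. Gaussian noise with standard deviation
#' `amplitude * robust_scale(x)` where the robust scale is `IQR(x) / 1.349`
#' (falling back to the SD and then to 1 for degenerate tensors). Works on
#' tensors of any shape; draws from the current RNG stream.
#'
#' @param x Numeric array/matrix/vector.
#' @param amplitude Noise SD in robust-scale units (>= 0).
#' @return Perturbed tensor of the same shape.
#' @export
add_noise <- function(x, amplitude = 0.3) {
  stopifnot(amplitude >= 0)
  if (amplitude == 0) return(x)
  x + rnorm(length(x), 0, amplitude * robust_scale(x))
}

#' @rdname add_noise
#' @export
robust_scale <- function(x) {
  s <- diff(quantile(x, c(0.25, 0.75), names = FALSE)) / 1.349
  if (s <= 0 || !is.finite(s)) s <- sd(x)
  if (is.na(s) || s <= 0) s <- 1
  s
}
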