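#' Loss weights and consistency ramp
#'
#' The total training objective is
#' `L = L_ce + omega(epoch) * L_consis + a * L_recon`, where `omega` ramps
#' smoothly from 0 to `omega_max` over the first `ramp_fraction` of the
#' epochs (a sigmoid-shaped ramp, the usual mean-teacher warm-up) and `a`
#' weights the autoencoder reconstruction loss (default 0.5).
#'
#' @param omega_max Consistency weight ceiling (default 1).
#' @param a Reconstruction weight (default 0.5).
#' @param ramp_fraction Fraction of training over which omega ramps
#'   (default 0.4).
#' @return A list of class `"loss_weights"`.
#' @export
loss_weights <- function(omega_max = 1, a = 0.5, ramp_fraction = 0.4) {
  stopifnot(omega_max >= 0, a >= 0, ramp_fraction >= 0, ramp_fraction <= 1)
  structure(list(omega_max = omega_max, a = a, ramp_fraction = ramp_fraction),
            class = "loss_weights")
}

#' @rdname loss_weights
#' @param epoch Zero-based epoch index.
#' @param n_epochs Total epochs.
#' @param weights A [loss_weights()].
#' @export
omega_schedule <- function(epoch, n_epochs, weights) {
  ramp_len <- weights$ramp_fraction * n_epochs
  if (ramp_len <= 0) return(weights$omega_max)
  t <- pmin(pmax(epoch / ramp_len, 0), 1)
  # smooth ramp, exactly 0 at t = 0 and omega_max at t = 1
  raw <- exp(-5 * (1 - t)^2)
  weights$omega_max * (raw - exp(-5)) / (1 - exp(-5))
}

#' Autoencoder reconstruction loss (binary cross-entropy)
#'
#' Mean elementwise binary cross-entropy between the reconstruction and the
#' min-max-normalized AE input, averaged over the batch and the 384
#' feature dimensions.
#'
#' @param inputs_01 M x K matrix with entries in `[0, 1]`.
#' @param reconstructions M x K matrix with entries in (0, 1).
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(inputs_01, reconstructions) {
  x <- as.matrix(inputs_01)
  r <- as.matrix(reconstructions)
  if (!identical(dim(x), dim(r))) abort("input/reconstruction shape mismatch")
  if (any(x < 0 | x > 1)) abort("inputs must lie in [0, 1]")
  if (any(r <= 0 | r >= 1)) abort("reconstructions must lie in (0, 1)")
  -mean(x * log(r) + (1 - x) * log(1 - r))
}

#' Supervised cross-entropy loss on labeled items
#'
#' Mean binary cross-entropy between predicted class probabilities and the
#' true labels. An empty labeled batch yields 0 with a warning.
#'
#' @param probs M x 2 matrix, rows on the simplex; column 2 is the positive
#'   ("lie") class.
#' @param labels Integer/logical vector (1 = lie, 0 = truth) or character
#'   labels in \{"truth", "lie"\}.
#' @return Non-negative scalar.
#' @export
supervised_loss <- function(probs, labels) {
  if (length(labels) == 0L) {
    warn("empty labeled batch: supervised loss is 0")
    return(0)
  }
  y <- label_to_int(labels)
  p <- pmin(pmax(as.matrix(probs)[, 2L], 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

label_to_int <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "lie")
  } else {
    as.integer(labels)
  }
}

#' Consistency regularization loss
#'
#' Mean over the batch of the squared Euclidean distance between the
#' student's fused output on the perturbed unlabeled input and the
#' teacher's fused output on the same (unperturbed) input.
#'
#' @param student_out,teacher_out M x D matrices.
#' @return Non-negative scalar.
#' @export
consistency_loss <- function(student_out, teacher_out) {
  s <- as.matrix(student_out)
  t <- as.matrix(teacher_out)
  if (!identical(dim(s), dim(t))) abort("student/teacher output shape mismatch")
  mean(rowSums((s - t)^2))
}

#' Total multi-part training loss
#'
#' `L_ce + omega(epoch) * L_consis + a * L_recon` with the consistency
#' weight from [omega_schedule()].
#'
#' @param parts Named list or vector with `ce`, `consis`, `recon`.
#' @param weights A [loss_weights()].
#' @param epoch Zero-based epoch index.
#' @param n_epochs Total epochs.
#' @return Scalar total loss.
#' @export
total_loss <- function(parts, weights, epoch, n_epochs) {
  parts <- as.list(parts)
  if (any(unlist(parts[c("ce", "consis", "recon")]) < 0)) {
    abort("negative component loss: invariant breach")
  }
  omega <- omega_schedule(epoch, n_epochs, weights)
  parts$ce + omega * parts$consis + weights$a * parts$recon
}

#' Classification metrics
#'
#' Accuracy, F1 (with "lie" as the positive class,
#' `f1 = 2 TP / (2 TP + FP + FN)`) and the 2x2 confusion matrix
#' (rows = truth labels, columns = predictions).
#'
#' @param predictions,truth Vectors of labels in \{"truth", "lie"\} (or
#'   0/1 with 1 = lie).
#' @return List: `accuracy`, `f1`, `confusion`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  if (length(truth) == 0L) abort("empty evaluation set")
  if (length(predictions) != length(truth)) abort("length mismatch")
  yp <- label_to_int(predictions)
  yt <- label_to_int(truth)
  tp <- sum(yp == 1 & yt == 1)
  fp <- sum(yp == 1 & yt == 0)
  fn <- sum(yp == 0 & yt == 1)
  tn <- sum(yp == 0 & yt == 0)
  conf <- matrix(c(tn, fp, fn, tp), 2L, 2L, byrow = TRUE,
                 dimnames = list(truth = c("truth", "lie"),
                                 predicted = c("truth", "lie")))
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(accuracy = mean(yp == yt), f1 = f1, confusion = conf)
}
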