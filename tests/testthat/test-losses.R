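test_that("reconstruction BCE matches closed forms and a brute-force sum", {
  x01 <- matrix(rep(c(0, 1), 6), 3, 4)
  expect_equal(reconstruction_loss(x01, abs(x01 - 1e-12)), 0, tolerance = 1e-9)
  half <- matrix(0.5, 3, 4)
  expect_equal(reconstruction_loss(half, half), log(2))
  set.seed(6)
  xs <- matrix(runif(15), 3, 5)
  rs <- matrix(runif(15, 0.05, 0.95), 3, 5)
  brute <- 0
  for (i in 1:3) for (j in 1:5) {
    brute <- brute - (xs[i, j] * log(rs[i, j]) +
                      (1 - xs[i, j]) * log(1 - rs[i, j]))
  }
  expect_equal(reconstruction_loss(xs, rs), brute / 15, tolerance = 1e-10)
  expect_error(reconstruction_loss(xs * 2, rs), "\\[0, 1\\]")
  expect_error(reconstruction_loss(xs, rs * 2), "\\(0, 1\\)")
})

test_that("supervised cross-entropy matches closed forms and a brute force", {
  perfect <- rbind(c(1e-12, 1 - 1e-12), c(1 - 1e-12, 1e-12))
  expect_equal(supervised_loss(perfect, c("lie", "truth")), 0,
               tolerance = 1e-9)
  uniform <- matrix(0.5, 4, 2)
  expect_equal(supervised_loss(uniform, c(1, 0, 1, 0)), log(2))
  set.seed(7)
  p2 <- runif(6, 0.05, 0.95)
  probs <- cbind(1 - p2, p2)
  y <- rbinom(6, 1, 0.5)
  brute <- -mean(y * log(p2) + (1 - y) * log(1 - p2))
  expect_equal(supervised_loss(probs, y), brute, tolerance = 1e-10)
  expect_warning(z <- supervised_loss(probs[0, , drop = FALSE], integer(0)),
                 "empty")
  expect_equal(z, 0)
})

test_that("consistency loss is the batch mean of squared distances", {
  s <- matrix(rnorm(12), 4, 3)
  expect_equal(consistency_loss(s, s), 0)
  t <- s
  v <- c(1, -2, 0.5)
  t[2, ] <- t[2, ] + v
  expect_equal(consistency_loss(s, t), sum(v^2) / 4, tolerance = 1e-12)
  set.seed(8)
  a <- matrix(rnorm(40), 8, 5)
  b <- matrix(rnorm(40), 8, 5)
  expect_gte(consistency_loss(a, b), 0)
  expect_error(consistency_loss(a, b[, 1:3]), "mismatch")
})

test_that("the total loss combines parts with the scheduled weights", {
  w <- loss_weights(omega_max = 0.5, a = 0.5, ramp_fraction = 0.4)
  # past the ramp: omega = omega_max
  expect_equal(total_loss(list(ce = 1, consis = 2, recon = 3), w,
                          epoch = 10, n_epochs = 10), 3.5)
  w0 <- loss_weights(omega_max = 0, a = 0)
  expect_equal(total_loss(list(ce = 1.3, consis = 9, recon = 9), w0, 5, 10),
               1.3)
  expect_error(total_loss(list(ce = -1, consis = 0, recon = 0), w, 1, 10),
               "negative")
})

test_that("the consistency ramp starts at 0, ends at omega_max, monotone", {
  w <- loss_weights(omega_max = 2, ramp_fraction = 0.5)
  om <- vapply(0:20, omega_schedule, numeric(1), n_epochs = 20, weights = w)
  expect_equal(om[1], 0)
  expect_equal(om[11], 2)       # ramp ends at epoch 10 of 20
  expect_equal(om[21], 2)
  expect_true(all(diff(om) >= -1e-12))
})

test_that("accuracy and F1 follow their defining formulas", {
  perfect <- evaluate_predictions(c("lie", "truth"), c("lie", "truth"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  # TP = 3, FP = 1, FN = 2, TN = 4 -> f1 = 6/9
  pred <- c(rep("lie", 3), "lie", rep("truth", 2), rep("truth", 4))
  truth <- c(rep("lie", 3), "truth", rep("lie", 2), rep("truth", 4))
  m <- evaluate_predictions(pred, truth)
  expect_equal(m$f1, 6 / 9, tolerance = 1e-12)
  expect_equal(m$accuracy, 7 / 10)
  expect_equal(unname(m$confusion),
               matrix(c(4, 1, 2, 3), 2, 2, byrow = TRUE))
  # permuting the class labels preserves accuracy but not F1
  swap <- function(x) ifelse(x == "lie", "truth", "lie")
  ms <- evaluate_predictions(swap(pred), swap(truth))
  expect_equal(ms$accuracy, m$accuracy)
  expect_false(isTRUE(all.equal(ms$f1, m$f1)))
  expect_error(evaluate_predictions(character(0), character(0)), "empty")
})
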