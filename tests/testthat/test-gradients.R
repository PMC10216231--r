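# Finite-difference validation of the backward passes: central differences
# of the combined loss (cross-entropy + consistency + reconstruction) on a
# miniature two-branch model must agree with backpropagation to 1e-4
# relative error, across every layer type (conv W/b, BN gamma/beta, dense
# encoder/decoder weights, fusion head).

rel_err <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-8)

test_that("backpropagated gradients match finite differences everywhere", {
  m <- tiny_model(seed = 5L)
  g <- tiny_grads(m, m$params)
  checks <- list(
    list(c("cnn", "c1", "W"), 7L), list(c("cnn", "c1", "W"), 20L),
    list(c("cnn", "c5", "W"), 3L), list(c("cnn", "c9", "W"), 1L),
    list(c("cnn", "bn1", "gamma"), 2L), list(c("cnn", "bn1", "beta"), 1L),
    list(c("cnn", "bn7", "gamma"), 1L), list(c("cnn", "bn9", "beta"), 2L),
    list(c("ae", "enc1", "W"), 11L), list(c("ae", "enc4", "W"), 5L),
    list(c("ae", "enc_bn2", "gamma"), 3L), list(c("ae", "enc_bn4", "beta"), 2L),
    list(c("ae", "dec1", "W"), 9L), list(c("ae", "dec4", "W"), 30L),
    list(c("ae", "dec4", "b"), 4L), list(c("ae", "dec_bn3", "gamma"), 5L),
    list(c("head", "W"), 3L), list(c("head", "b"), 1L)
  )
  for (ck in checks) {
    path <- ck[[1]]
    idx <- ck[[2]]
    ana <- g[[path]][idx]
    num <- tiny_fd(m, m$params, path, idx)
    expect_lt(rel_err(ana, num), 1e-4,
              label = sprintf("gradient of %s[%d] (analytic %.3e vs fd %.3e)",
                              paste(path, collapse = "$"), idx, ana, num))
  }
})

test_that("conv bias gradients vanish under batch normalisation", {
  # a per-channel constant shift is removed by the following BN, so the
  # bias direction is flat in the loss
  m <- tiny_model(seed = 6L)
  g <- tiny_grads(m, m$params)
  expect_lt(max(abs(g$cnn$c2$b)), 1e-10)
})

test_that("the consistency penalty reaches the branches but not the head", {
  m <- tiny_model(seed = 8L)
  g1 <- tiny_grads(m, m$params)
  m0 <- m
  r <- tiny_loss(m, m$params)
  m0$tea <- r$fused                       # teacher equals student exactly
  g0 <- tiny_grads(m0, m0$params)
  # the consistency residual drives the encoder branches ...
  expect_false(isTRUE(all.equal(g1$ae$enc1$W, g0$ae$enc1$W)))
  expect_false(isTRUE(all.equal(g1$cnn$c1$W, g0$cnn$c1$W)))
  # ... but bypasses the classifier head (fused-embedding mode), whose
  # gradient stays the pure cross-entropy gradient either way
  expect_equal(g1$head$W, g0$head$W, tolerance = 1e-12)
  fd <- tiny_fd(m0, m0$params, c("head", "W"), 2L)
  expect_lt(rel_err(g0$head$W[2L], fd), 1e-4)
})
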