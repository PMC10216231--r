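test_that("the full-scale CNN reproduces the printed layer shape table", {
  tr <- cnn_shape_trace(cnn_spec("full"))
  got <- tr[, c("h", "w", "c")]
  expected <- rbind(
    c(256, 256, 3),
    c(256, 256, 32), c(256, 256, 32), c(256, 256, 32),
    c(128, 128, 32),                                    # max-pool
    c(128, 128, 64), c(128, 128, 64), c(128, 128, 64),
    c(64, 64, 64),                                      # max-pool
    c(62, 62, 128),                                     # unpadded conv
    c(62, 62, 64), c(62, 62, 32),
    c(1, 1, 32),                                        # sum-and-average
    c(1, 1, 8))                                         # full connection
  expect_equal(unname(as.matrix(got)), unname(expected))
})

test_that("the desk-scale spec propagates shapes by the same rules", {
  tr <- cnn_shape_trace(cnn_spec("desk"))
  expect_equal(tr$h[1], 64)
  expect_equal(tr$h[tr$layer == "max-pool"], c(32, 16))
  expect_equal(tr$h[grepl("conv7", tr$layer)], 14)      # 16 - 2, unpadded
  expect_equal(tr$c[tr$layer == "global-average"],
               cnn_spec("desk")$emb_dim)
})

test_that("an actual forward pass matches the traced embedding width", {
  spec <- cnn_spec("desk")
  set.seed(2)
  p <- cnn_init(spec)
  x <- array(rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  f <- cnn_forward(x, p, spec, train = FALSE)
  expect_equal(dim(f$emb), c(2L, spec$emb_dim))
  expect_equal(dim(f$aux), c(2L, 8L))
  # eval-mode determinism
  expect_identical(f$emb, cnn_forward(x, p, spec, train = FALSE)$emb)
  # wrong input shape names expected vs got
  expect_error(cnn_forward(array(0, c(32, 32, 3, 1)), p, spec),
               "expected 64x64x3")
})

test_that("the AE honours the printed widths: bottleneck 32, output 384", {
  spec <- ae_spec()
  expect_equal(spec$enc, c(256L, 128L, 64L, 32L))
  expect_equal(spec$dec, c(128L, 180L, 256L, 384L))
  set.seed(3)
  p <- ae_init(spec)
  x <- matrix(runif(5 * 384), 5, 384)
  f <- ae_forward(x, p, spec, train = FALSE)
  expect_equal(dim(f$bottleneck), c(5L, 32L))
  expect_equal(dim(f$recon), c(5L, 384L))
  expect_true(all(f$recon > 0 & f$recon < 1))
  expect_equal(dim(f$aux), c(5L, 8L))
  expect_identical(f$bottleneck,
                   ae_forward(x, p, spec, train = FALSE)$bottleneck)
  expect_error(ae_forward(matrix(0, 2, 100), p, spec), "expected 384")
})

test_that("fusion + softmax behaves like the closed form", {
  set.seed(4)
  head <- fusion_init(8L)
  ae_emb <- matrix(rnorm(3 * 4), 3, 4)
  cnn_emb <- matrix(rnorm(3 * 4), 3, 4)
  r <- fuse_and_classify(ae_emb, cnn_emb, head)
  expect_equal(rowSums(r$probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(r$probs >= 0))
  # zero weights: uniform probabilities
  head0 <- list(W = matrix(0, 8, 2), b = c(0, 0))
  r0 <- fuse_and_classify(ae_emb, cnn_emb, head0)
  expect_equal(unname(r0$probs), matrix(0.5, 3, 2))
  # logits (l, l + c) give probability ratio e^c
  head_c <- list(W = matrix(0, 8, 2), b = c(1, 1 + 0.7))
  rc <- fuse_and_classify(ae_emb, cnn_emb, head_c)
  expect_equal(rc$probs[, 2] / rc$probs[, 1], rep(exp(0.7), 3),
               tolerance = 1e-12)
  expect_error(fuse_and_classify(matrix(0, 2, 4), matrix(0, 3, 4), head),
               "batch size")
})

test_that("the EMA update matches its closed form and checks congruence", {
  tea <- list(a = matrix(2, 3, 3), nested = list(b = rep(4, 5)))
  stu <- list(a = matrix(0, 3, 3), nested = list(b = rep(0, 5)))
  expect_identical(ema_update(tea, stu, 1), tea)        # frozen teacher
  expect_identical(ema_update(tea, stu, 0), stu)        # hard copy
  # geometric contraction over k steps with a constant student
  cur <- tea
  for (k in 1:10) cur <- ema_update(cur, stu, 0.99)
  expect_equal(cur$a, matrix(2 * 0.99^10, 3, 3), tolerance = 1e-10)
  expect_equal(cur$nested$b, rep(4 * 0.99^10, 5), tolerance = 1e-10)
  # equality is preserved: teacher == student stays equal after an update
  expect_identical(ema_update(stu, stu, 0.99), stu)
  expect_error(ema_update(tea, list(a = matrix(0, 3, 3)), 0.5), "congruent")
  expect_error(ema_update(tea, list(a = matrix(0, 2, 2),
                                    nested = list(b = rep(0, 5))), 0.5),
               "congruent")
})
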