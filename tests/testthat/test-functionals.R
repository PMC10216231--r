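test_that("functionals of a constant series take their degenerate values", {
  f <- apply_functionals(rep(4.2, 25))
  expect_equal(unname(f[c("mean", "max", "min", "offset")]), rep(4.2, 4))
  expect_equal(unname(f[c("stddev", "kurtosis", "skewness", "range",
                          "slope", "mse")]), rep(0, 6))
  expect_equal(unname(f["maxposition"]), 0)   # first extremum
})

test_that("a linear series has exact least-squares functionals", {
  f <- apply_functionals(c(0, 1, 2, 3))
  expect_equal(unname(f["slope"]), 3)
  expect_equal(unname(f["offset"]), 0, tolerance = 1e-12)
  expect_equal(unname(f["mse"]), 0, tolerance = 1e-12)
  expect_equal(unname(f["maxposition"]), 1)
  expect_equal(unname(f["minposition"]), 0)
})

test_that("series of length < 2 are rejected", {
  expect_error(apply_functionals(3), "length")
})

test_that("all 12 functionals match an independent brute-force oracle", {
  set.seed(33)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(2:200, 1)
    x <- switch(1 + i %% 4,
                rnorm(n),
                rexp(n),
                cumsum(rnorm(n)),
                round(runif(n), 1))          # includes ties
    worst <- max(worst, max(abs(apply_functionals(x) - brute_functionals(x))))
  }
  expect_lt(worst, 1e-8)
})

test_that("the IS09 vector is 384-dimensional, finite and deterministic", {
  wav <- synthesize_once(seed = 21L)
  v <- extract_is09(wav)
  expect_length(v, 384L)
  expect_true(all(is.finite(v)))
  expect_identical(v, extract_is09(wav))
  # silence is degenerate but still finite and full-length
  v0 <- extract_is09(waveform(rep(0, 48000), 48000L))
  expect_length(v0, 384L)
  expect_true(all(is.finite(v0)))
  # layout: 12 functionals of LLD then of its delta, per descriptor
  expect_equal(names(v)[1], "zcr_mean")
  expect_equal(names(v)[13], "zcr_de_mean")
  expect_equal(names(v)[384], "mfcc12_de_mse")
})

test_that("the corpus feature extractor aligns IS09 rows and mel tensors", {
  sc <- small_corpus()
  feats <- fixture("small_features", function() {
    extract_features(sc$manifest, size = 64L)
  })
  expect_equal(nrow(feats$is09), 12L)
  expect_equal(ncol(feats$is09), 385L)            # id + 384
  expect_equal(names(feats$mel), feats$is09$id)
  expect_equal(dim(feats$mel[[1]]), c(64L, 64L, 3L))
  # cache round trip
  dir <- withr::local_tempdir()
  write_feature_cache(feats, dir)
  back <- read_feature_cache(dir)
  expect_equal(as.data.frame(back$is09), as.data.frame(feats$is09),
               tolerance = 1e-12)
  expect_equal(back$mel, feats$mel)
})
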