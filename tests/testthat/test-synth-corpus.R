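test_that("zero class separation makes the classes indistinguishable", {
  truth <- f0_mean_draws(60, "truth", separation = 0, seed = 100L)
  lie <- f0_mean_draws(60, "lie", separation = 0, seed = 200L)
  expect_gt(suppressWarnings(stats::ks.test(truth, lie)$p.value), 0.01)
})

test_that("large separation shifts the mean F0 functional by > 2 pooled SDs", {
  truth <- f0_mean_draws(100, "truth", separation = 3, seed = 300L)
  lie <- f0_mean_draws(100, "lie", separation = 3, seed = 301L)
  pooled <- sqrt((var(truth) + var(lie)) / 2)
  expect_gt((mean(lie) - mean(truth)) / pooled, 2)
})

test_that("synthesis is deterministic given seed and arguments", {
  w1 <- synthesize_once(seed = 77L, class_label = "lie")
  w2 <- synthesize_once(seed = 77L, class_label = "lie")
  expect_identical(w1, w2)
})

test_that("corpus generation writes a manifest with the configured counts", {
  sc <- small_corpus()
  man <- sc$manifest
  expect_equal(nrow(man), 12L)
  expect_true(all(file.exists(man$path)))
  # class counts match deception_fraction to within rounding
  expect_equal(sum(man$hidden_label == "lie"),
               round(12 * sc$cfg$deception_fraction))
  # exactly n_labeled training items carry visible labels
  expect_equal(sum(man$labeled & man$split == "train"), 8L)
  expect_true(all(is.na(man$label[!man$labeled])))
  expect_true(all(man$labeled[man$split == "test"]))
  # re-generation under the same seed is byte-identical
  dir2 <- withr::local_tempdir()
  man2 <- generate_corpus(sc$cfg, dir2)
  expect_equal(man2$hidden_label, man$hidden_label)
  expect_identical(unname(tools::md5sum(man2$path)),
                   unname(tools::md5sum(man$path)))
})

test_that("a fully labeled manifest has no unlabeled training items", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_utterances = 10L, n_labeled = 10L,
                      duration_s = c(0.5, 1), seed = 5L)
  man <- generate_corpus(cfg, dir)
  expect_true(all(man$labeled))
  expect_false(anyNA(man$label))
})

test_that("the 9:1 split reproduces 992/111 from 1,103 and partitions", {
  man <- tibble::tibble(id = sprintf("u%04d", 1:1103),
                        hidden_label = rep(c("lie", "truth"), c(521, 582)),
                        split = NA_character_)
  sp <- split_train_test(man, train_ratio = 0.9, seed = 3L)
  expect_equal(sum(sp$split == "train"), 992L)
  expect_equal(sum(sp$split == "test"), 111L)
  # stratification: test-set class balance close to the corpus balance
  expect_equal(sum(sp$split == "test" & sp$hidden_label == "lie"),
               round(111 * 521 / 1103), tolerance = 1)
  # small case: floor(0.9 * 10) = 9
  man10 <- tibble::tibble(id = as.character(1:10),
                          hidden_label = rep(c("lie", "truth"), 5),
                          split = NA)
  sp10 <- split_train_test(man10, 0.9, seed = 1L)
  expect_equal(sum(sp10$split == "train"), 9L)
  expect_error(split_train_test(man10[1, ], 0.9), "at least 2")
})

test_that("train and test partition the corpus exactly", {
  man <- small_corpus()$manifest
  expect_setequal(c(man$id[man$split == "train"], man$id[man$split == "test"]),
                  man$id)
  expect_length(intersect(man$id[man$split == "train"],
                          man$id[man$split == "test"]), 0)
})

test_that("linear-probe separability is monotone in class_separation", {
  accs <- fixture("probe_grid", function() {
    vapply(c(0, 1, 2, 3), function(sep) {
      dir <- file.path(tempdir(), sprintf("deceptr-grid-%d", sep * 10))
      # 50/50 split so the probe is scored on 100 held-out utterances
      cfg <- synth_config(n_utterances = 200L, n_labeled = 100L,
                          duration_s = c(0.8, 1.5), class_separation = sep,
                          noise_level = 0.01, seed = 500L)
      man <- generate_corpus(cfg, dir, train_ratio = 0.5)
      feats <- extract_features(man, what = "is09")
      is09_linear_probe(feats, man)$accuracy
    }, numeric(1))
  })
  expect_true(all(diff(accs) >= -1e-9))
  expect_lt(accs[1], 0.8)     # no separation: near chance
  expect_gt(accs[4], 0.8)     # strong separation: clearly separable
})
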