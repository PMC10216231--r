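# Trainer behaviour on a tiny separable toy problem: synthetic feature
# objects are built directly (no audio) so these tests run in seconds.

toy_problem <- function(n = 24L, n_test = 8L, seed = 99L, gap = 3) {
  set.seed(seed)
  ids <- sprintf("t%03d", seq_len(n + n_test))
  lab <- rep(c("truth", "lie"), length.out = n + n_test)
  shift <- ifelse(lab == "lie", gap, 0)
  is09 <- matrix(rnorm((n + n_test) * 384), n + n_test, 384) +
    outer(shift, c(rep(1, 40), rep(0, 344)))
  colnames(is09) <- paste0("f", seq_len(384))
  mel <- lapply(seq_len(n + n_test), function(i) {
    base <- array(rnorm(64 * 64 * 3, sd = 0.5), c(64, 64, 3))
    base[20:40, 20:40, 1] <- base[20:40, 20:40, 1] + shift[i]
    base
  })
  names(mel) <- ids
  feats <- structure(list(
    is09 = dplyr::bind_cols(tibble::tibble(id = ids),
                            tibble::as_tibble(is09)),
    mel = mel, size = 64L, params = list()), class = "corpus_features")
  man <- tibble::tibble(id = ids, path = "", label = lab,
                        hidden_label = lab,
                        split = rep(c("train", "test"), c(n, n_test)),
                        labeled = TRUE)
  list(manifest = man, features = feats)
}

test_that("supervised-only training reduces the loss on separable data", {
  tp <- toy_problem()
  cfg <- train_config(epochs = 8L, batch_size = 8L,
                      labeled_batch_fraction = 1, dropout = 0,
                      weights = loss_weights(omega_max = 0, a = 0),
                      use_ae = TRUE, use_cnn = FALSE, seed = 2L,
                      lr = 3e-3)
  f <- fit_aemt(tp$manifest, tp$features, cfg)
  h <- f$history
  expect_equal(nrow(h), 8L)
  expect_lt(mean(tail(h$loss_ce, 2)), mean(head(h$loss_ce, 2)))
  expect_gt(max(h$test_accuracy), 0.7)
})

test_that("the learning rate follows the cosine schedule endpoints", {
  expect_equal(cosine_lr(0, 15, 3e-4), 3e-4)
  expect_equal(cosine_lr(14, 15, 3e-4), 0, tolerance = 1e-18)
  expect_true(all(diff(vapply(0:14, cosine_lr, numeric(1), n_epochs = 15,
                              lr0 = 3e-4)) < 0))
})

test_that("one train_step applies the EMA wiring exactly", {
  tp <- toy_problem(n = 8L, n_test = 2L)
  cfg <- train_config(epochs = 2L, batch_size = 4L, seed = 3L)
  norm <- compute_norm(tp$features, tp$manifest$id[tp$manifest$split == "train"])
  state <- init_model_state(cfg, norm)
  is09 <- normalize_is09(tp$features, norm)
  mel <- normalize_mel(tp$features, norm)
  tea_before <- state$teacher$cnn
  set.seed(4)
  batch <- list(lab_mel = mel[1:2], lab_is09 = is09[1:2, ],
                labels = tp$manifest$label[1:2],
                unlab_mel = mel[3:4], unlab_is09 = is09[3:4, ])
  r <- train_step(batch, state, cfg, epoch = 1L, n_epochs = 2L)
  expected <- ema_update(tea_before, r$state$student$cnn, cfg$alpha_ema)
  expect_equal(r$state$teacher$cnn, expected, tolerance = 1e-12)
  expect_true(all(unlist(r$losses[c("ce", "consis", "recon")]) >= 0))
})

test_that("identical seeds give identical loss traces and predictions", {
  tp <- toy_problem()
  cfg <- train_config(epochs = 3L, seed = 42L)
  f1 <- fit_aemt(tp$manifest, tp$features, cfg)
  f2 <- fit_aemt(tp$manifest, tp$features, cfg)
  expect_equal(f1$history, f2$history, tolerance = 1e-15)
  p1 <- predict(f1, tp$features)
  p2 <- predict(f2, tp$features)
  expect_equal(p1, p2, tolerance = 1e-15)
})

test_that("training fails cleanly with zero labeled items", {
  tp <- toy_problem(n = 10L, n_test = 2L)
  tp$manifest$labeled[tp$manifest$split == "train"] <- FALSE
  tp$manifest$label[!tp$manifest$labeled] <- NA
  expect_error(fit_aemt(tp$manifest, tp$features, train_config(epochs = 1L)),
               "no labeled")
})

test_that("hidden labels of unlabeled items are never read in training", {
  tp <- toy_problem()
  tp$manifest$labeled[tp$manifest$split == "train"][1:12] <- FALSE
  tp$manifest$label[!tp$manifest$labeled] <- NA
  cfg <- train_config(epochs = 3L, seed = 7L)
  f1 <- fit_aemt(tp$manifest, tp$features, cfg)
  poisoned <- tp$manifest
  poisoned$hidden_label[!poisoned$labeled] <-
    rev(poisoned$hidden_label[!poisoned$labeled])
  f2 <- fit_aemt(poisoned, tp$features, cfg)
  expect_equal(f1$history, f2$history, tolerance = 1e-15)
})

test_that("checkpoints round-trip to identical evaluation metrics", {
  tp <- toy_problem()
  f <- fit_aemt(tp$manifest, tp$features, train_config(epochs = 2L, seed = 8L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(f, path)
  back <- load_checkpoint(path)
  e1 <- evaluate_aemt(f, tp$manifest, tp$features)
  e2 <- evaluate_aemt(back, tp$manifest, tp$features)
  expect_equal(e1$accuracy, e2$accuracy)
  expect_equal(e1$f1, e2$f1)
  expect_equal(e1$confusion, e2$confusion)
})

test_that("ablation variants wire the branches and losses as named", {
  cfg <- train_config(weights = loss_weights(omega_max = 1.5, a = 0.5))
  mt <- variant_config(cfg, "MT", 1L)
  expect_false(mt$use_ae); expect_true(mt$use_cnn)
  expect_equal(mt$weights$a, 0); expect_equal(mt$weights$omega_max, 1.5)
  ae <- variant_config(cfg, "AE", 1L)
  expect_true(ae$use_ae); expect_false(ae$use_cnn)
  expect_equal(ae$weights$omega_max, 0); expect_equal(ae$weights$a, 0.5)
  both <- variant_config(cfg, "AE+MT", 1L)
  cr <- variant_config(cfg, "AE+MT+CR", 1L)
  # AE+MT+CR differs from AE+MT only by the consistency weight
  both$weights$omega_max <- cr$weights$omega_max
  expect_identical(both, cr)
  tp <- toy_problem(n = 6L, n_test = 2L)
  expect_error(run_ablation(tp$manifest, tp$features, cfg,
                            variants = "bogus"),
               "unknown variant")
})

test_that("tidy/glance/autoplot expose the training history", {
  tp <- toy_problem()
  f <- fit_aemt(tp$manifest, tp$features, train_config(epochs = 2L, seed = 5L))
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2L)
  gl <- glance(f)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("best_accuracy", "best_f1", "epochs") %in% names(gl)))
  expect_s3_class(ggplot2::autoplot(f), "ggplot")
})
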