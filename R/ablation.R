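#' Ablation runner
#'
#' Re-trains the model with components removed — `"MT"` (mean-teacher CNN
#' only, supervised + consistency losses), `"AE"` (autoencoder only,
#' supervised + reconstruction losses), `"AE+MT"` (both branches, no
#' consistency) and `"AE+MT+CR"` (the full model) — at each labeled budget,
#' and tabulates test accuracy and F1.
#'
#' @param manifest Corpus manifest tibble.
#' @param features Matching `"corpus_features"`.
#' @param cfg Base [train_config()]; each variant adjusts `use_ae`,
#'   `use_cnn` and `omega_max` from it.
#' @param variants Subset of `c("MT", "AE", "AE+MT", "AE+MT+CR")`.
#' @param label_budgets Labeled-training-set sizes to sweep; `NULL` keeps
#'   the manifest's labeled set as is.
#' @param seeds Integer vector of seeds; each (variant, budget) cell is run
#'   once per seed.
#' @param verbose Print one line per run.
#' @return Tibble: `variant`, `n_labeled`, `seed`, `accuracy`, `f1`.
#' @export
run_ablation <- function(manifest, features, cfg = train_config(),
                         variants = c("MT", "AE", "AE+MT", "AE+MT+CR"),
                         label_budgets = NULL, seeds = cfg$seed,
                         verbose = FALSE) {
  known <- c("MT", "AE", "AE+MT", "AE+MT+CR")
  if (!all(variants %in% known)) {
    abort(paste0("unknown variant: ",
                 paste(setdiff(variants, known), collapse = ", ")))
  }
  if (is.null(label_budgets)) {
    label_budgets <- sum(manifest$split == "train" & manifest$labeled)
  }
  out <- list()
  for (budget in label_budgets) {
    man_b <- restrict_label_budget(manifest, budget, seed = cfg$seed)
    for (variant in variants) {
      for (seed in seeds) {
        cfg_v <- variant_config(cfg, variant, seed)
        f <- fit_aemt(man_b, features, cfg_v)
        h <- f$history
        best <- which.max(h$test_accuracy)
        out[[length(out) + 1L]] <- tibble(
          variant = variant, n_labeled = budget, seed = seed,
          accuracy = h$test_accuracy[best], f1 = h$test_f1[best])
        if (verbose) {
          message(sprintf("  %-9s n_labeled=%d seed=%d acc=%.3f f1=%.3f",
                          variant, budget, seed,
                          h$test_accuracy[best], h$test_f1[best]))
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

variant_config <- function(cfg, variant, seed) {
  cfg$seed <- as.integer(seed)
  w <- cfg$weights
  switch(variant,
    "MT" = {
      cfg$use_ae <- FALSE; cfg$use_cnn <- TRUE
      cfg$weights <- loss_weights(w$omega_max, a = 0, w$ramp_fraction)
    },
    "AE" = {
      cfg$use_ae <- TRUE; cfg$use_cnn <- FALSE
      cfg$weights <- loss_weights(0, a = w$a, w$ramp_fraction)
    },
    "AE+MT" = {
      cfg$use_ae <- TRUE; cfg$use_cnn <- TRUE
      cfg$weights <- loss_weights(0, a = w$a, w$ramp_fraction)
    },
    "AE+MT+CR" = {
      cfg$use_ae <- TRUE; cfg$use_cnn <- TRUE
      cfg$weights <- loss_weights(w$omega_max, a = w$a, w$ramp_fraction)
    })
  cfg
}

# shrink the visible labeled training set to `budget` items (stratified by
# label); test labels are untouched
restrict_label_budget <- function(manifest, budget, seed = 1L) {
  lab_train <- which(manifest$split == "train" & manifest$labeled)
  if (budget > length(lab_train)) {
    abort(sprintf("label budget %d exceeds available labeled items (%d)",
                  budget, length(lab_train)))
  }
  set.seed(seed + budget)
  keep <- stratified_sample(lab_train, manifest$label[lab_train], budget)
  drop <- setdiff(lab_train, keep)
  manifest$labeled[drop] <- FALSE
  manifest$label[drop] <- NA_character_
  manifest
}

#' Linear probe on IS09 features
#'
#' A ridge-regularised logistic regression (via glmnet) trained on the
#' labeled training items' IS09 vectors and evaluated on the test split —
#' the simple supervised reference against which the semi-supervised model
#' is judged, and the separability yardstick of the synthetic corpus.
#'
#' @param features A `"corpus_features"` object.
#' @param manifest Corpus manifest.
#' @param lambda Ridge penalty (default 0.01).
#' @return List: `accuracy`, `f1`, `n_train`, `n_test`.
#' @export
is09_linear_probe <- function(features, manifest, lambda = 0.01) {
  m <- as.matrix(features$is09[, -1L])
  rownames(m) <- features$is09$id
  tr <- manifest[manifest$split == "train" & manifest$labeled, ]
  te <- manifest[manifest$split == "test", ]
  sdv <- apply(m[tr$id, , drop = FALSE], 2L, sd)
  keep <- sdv > 1e-10
  fit <- glmnet::glmnet(m[tr$id, keep, drop = FALSE],
                        factor(tr$label, levels = c("truth", "lie")),
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = TRUE)
  p <- predict(fit, m[te$id, keep, drop = FALSE], type = "response")[, 1L]
  pred <- ifelse(p > 0.5, "lie", "truth")
  truth <- if ("hidden_label" %in% names(te)) te$hidden_label else te$label
  c(evaluate_predictions(pred, truth),
    list(n_train = nrow(tr), n_test = nrow(te)))
}
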