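#' Training configuration
#'
#' Hyperparameters of the semi-supervised AE + mean-teacher trainer: SGD
#' with momentum at learning rate 3e-4 under cosine annealing, dropout with
#' keep probability 0.8 (drop 0.2), EMA smoothing 0.99, and a batch mixing
#' one labeled item for every three unlabeled ones.
#'
#' @param epochs Number of epochs (<= 100).
#' @param batch_size Items per batch (labeled + unlabeled).
#' @param labeled_batch_fraction Fraction of each batch that is labeled.
#' @param lr Initial learning rate (default 3e-4).
#' @param momentum SGD momentum (default 0.9).
#' @param dropout Drop probability applied in the AE and the fusion head.
#'   The default 0.2 realises the prescribed dropout value 0.8 as a keep
#'   probability: dropping 80% of a 32-unit bottleneck destroys the
#'   representation and measurably caps accuracy below the supervised
#'   reference, while keeping 80% matches it.
#' @param alpha_ema Teacher EMA smoothing coefficient (default 0.99).
#' @param weights A [loss_weights()].
#' @param aug An [augment_config()].
#' @param scale CNN scale, `"desk"` (64x64) or `"full"` (256x256).
#' @param use_ae,use_cnn Enable the AE / mean-teacher branch (ablations).
#' @param consistency_on `"fused"` (default: squared distance between fused
#'   embeddings) or `"probs"` (between class probabilities).
#' @param seed Integer RNG seed; fixes batching, initialisation,
#'   augmentation and dropout.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(epochs = 15L, batch_size = 8L,
                         labeled_batch_fraction = 0.25,
                         lr = 3e-4, momentum = 0.9, dropout = 0.2,
                         alpha_ema = 0.99, weights = loss_weights(),
                         aug = augment_config(), scale = c("desk", "full"),
                         use_ae = TRUE, use_cnn = TRUE,
                         consistency_on = c("fused", "probs"), seed = 1L) {
  scale <- match.arg(scale)
  consistency_on <- match.arg(consistency_on)
  stopifnot(epochs >= 1, epochs <= 100, batch_size >= 2,
            labeled_batch_fraction > 0, labeled_batch_fraction <= 1,
            dropout >= 0, dropout < 1, alpha_ema >= 0, alpha_ema <= 1,
            use_ae || use_cnn)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 labeled_batch_fraction = labeled_batch_fraction,
                 lr = lr, momentum = momentum, dropout = dropout,
                 alpha_ema = alpha_ema, weights = weights, aug = aug,
                 scale = scale, use_ae = use_ae, use_cnn = use_cnn,
                 consistency_on = consistency_on, seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#' @param epoch Zero-based epoch index.
#' @param n_epochs Total epochs.
#' @param lr0 Initial learning rate.
#' @return Learning rate for `epoch`; `lr0` at epoch 0, 0 at the final one.
#' @export
cosine_lr <- function(epoch, n_epochs, lr0) {
  if (n_epochs <= 1L) return(lr0)
  lr0 * 0.5 * (1 + cos(pi * epoch / (n_epochs - 1)))
}

## ---- model state ---------------------------------------------------------

init_model_state <- function(cfg, norm) {
  cnn <- cnn_spec(cfg$scale)
  ae <- ae_spec()
  d_fused <- (if (cfg$use_ae) ae$bottleneck else 0L) +
             (if (cfg$use_cnn) cnn$emb_dim else 0L)
  student <- list()
  if (cfg$use_cnn) student$cnn <- cnn_init(cnn)
  if (cfg$use_ae) student$ae <- ae_init(ae)
  student$head <- fusion_init(d_fused)
  state <- list(spec = list(cnn = cnn, ae = ae),
                student = student,
                teacher = if (cfg$use_cnn) list(cnn = student$cnn) else list(),
                norm = norm, cfg = cfg)
  class(state) <- "aemt_state"
  state
}

# per-feature min-max over the training split (IS09) and per-channel
# mean/sd (mel); test-time values are clamped into [0, 1]
compute_norm <- function(features, train_ids) {
  m <- as.matrix(features$is09[, -1L])
  tr <- features$is09$id %in% train_ids
  lo <- apply(m[tr, , drop = FALSE], 2L, min)
  hi <- apply(m[tr, , drop = FALSE], 2L, max)
  rng <- pmax(hi - lo, 1e-8)
  mel_tr <- features$mel[names(features$mel) %in% train_ids]
  ch_mean <- ch_sd <- numeric(3L)
  for (ch in 1:3) {
    v <- vapply(mel_tr, function(a) c(mean(a[, , ch]), mean(a[, , ch]^2)),
                numeric(2L))
    ch_mean[ch] <- mean(v[1L, ])
    ch_sd[ch] <- sqrt(max(mean(v[2L, ]) - ch_mean[ch]^2, 1e-12))
  }
  list(is09_lo = lo, is09_rng = rng, mel_mean = ch_mean, mel_sd = ch_sd)
}

normalize_is09 <- function(features, norm) {
  m <- as.matrix(features$is09[, -1L])
  m <- sweep(sweep(m, 2L, norm$is09_lo), 2L, norm$is09_rng, "/")
  m <- pmin(pmax(m, 0), 1)
  rownames(m) <- features$is09$id
  m
}

normalize_mel <- function(features, norm) {
  lapply(features$mel, function(a) {
    for (ch in 1:3) a[, , ch] <- (a[, , ch] - norm$mel_mean[ch]) / norm$mel_sd[ch]
    a
  })
}

stack_mel <- function(mel_list) {
  d <- dim(mel_list[[1L]])
  array(unlist(mel_list, use.names = FALSE), c(d, length(mel_list)))
}

## ---- one optimisation step ----------------------------------------------

#' One semi-supervised training step
#'
#' Performs one SGD-with-momentum update of the student (CNN, AE and fusion
#' head) on the total loss, then one EMA update of the teacher CNN. The
#' batch carries labeled items (clean IS09 vectors, flip/crop-augmented
#' spectrograms) and unlabeled items (noise-enhanced student views, clean
#' teacher views).
#'
#' @param batch List with `lab_mel` (list of normalized mel arrays),
#'   `lab_is09` (matrix), `labels` (character), and `unlab_mel`,
#'   `unlab_is09` for the unlabeled part (may be NULL).
#' @param state An `"aemt_state"` model state.
#' @param cfg The [train_config()].
#' @param opt Optimiser state (momentum velocities); NULL on the first call.
#' @param epoch,n_epochs Zero-based epoch and total epochs (consistency
#'   ramp and learning-rate schedule).
#' @param pools Optional list of buffer-pool environments (`stu`, `tea`)
#'   reused across steps; [fit_aemt()] manages them.
#' @return List: `state`, `opt`, `losses` (ce, consis, recon, omega, lr,
#'   total).
#' @export
train_step <- function(batch, state, cfg, opt = NULL, epoch = 0L,
                       n_epochs = 1L, pools = NULL) {
  spec <- state$spec
  n_lab <- length(batch$labels)
  n_unlab <- if (is.null(batch$unlab_is09)) 0L else nrow(batch$unlab_is09)
  omega <- omega_schedule(epoch, n_epochs, cfg$weights)
  lr <- cosine_lr(epoch, n_epochs, cfg$lr)
  use_consis <- cfg$use_cnn && omega > 0 && n_unlab > 0L

  ## ---- augmentation (eta / eta' / eta'') ---------------------------------
  amp <- cfg$aug$noise_amplitude
  if (cfg$use_cnn) {
    lab_mel <- lapply(batch$lab_mel, flip_crop, cfg = cfg$aug)
    stu_unlab_mel <- lapply(batch$unlab_mel, function(a)
      add_noise(flip_crop(a, cfg$aug), amp))
    tea_unlab_mel <- lapply(batch$unlab_mel, flip_crop, cfg = cfg$aug)
  }
  if (cfg$use_ae) {
    ae_in <- rbind(batch$lab_is09,
                   if (n_unlab > 0L) noise_rows(batch$unlab_is09, amp))
    ae_target <- rbind(batch$lab_is09, batch$unlab_is09)  # denoising target
  }

  ## ---- student forward ---------------------------------------------------
  losses <- list(ce = 0, consis = 0, recon = 0)
  if (cfg$use_cnn) {
    x_cnn <- stack_mel(c(lab_mel, stu_unlab_mel))
    fwd_cnn <- cnn_forward(x_cnn, state$student$cnn, spec$cnn, train = TRUE,
                           pool = pools$stu)
    state$student$cnn <- fwd_cnn$params
    cnn_emb <- fwd_cnn$emb
  }
  if (cfg$use_ae) {
    fwd_ae <- ae_forward(ae_in, state$student$ae, spec$ae, train = TRUE,
                         p_drop = cfg$dropout)
    state$student$ae <- fwd_ae$params
    losses$recon <- reconstruction_loss(ae_target, fwd_ae$recon)
  }
  fused <- cbind(if (cfg$use_ae) fwd_ae$bottleneck,
                 if (cfg$use_cnn) cnn_emb)
  lab_rows <- seq_len(n_lab)
  head_fwd <- fuse_head_forward(fused[lab_rows, , drop = FALSE],
                                state$student$head, cfg$dropout, train = TRUE)
  losses$ce <- supervised_loss(head_fwd$probs, batch$labels)

  ## ---- teacher forward (no gradient) -------------------------------------
  if (use_consis) {
    tea_cnn <- cnn_forward(stack_mel(tea_unlab_mel), state$teacher$cnn,
                           spec$cnn, train = TRUE, keep_cache = FALSE,
                           pool = pools$tea)$emb
    tea_ae <- if (cfg$use_ae) {
      ae_forward(batch$unlab_is09, state$student$ae, spec$ae,
                 train = FALSE)$bottleneck
    }
    tea_fused <- cbind(tea_ae, tea_cnn)
    stu_unlab_fused <- fused[n_lab + seq_len(n_unlab), , drop = FALSE]
    if (cfg$consistency_on == "probs") {
      stu_p <- fuse_head_forward(stu_unlab_fused, state$student$head,
                                 cfg$dropout, train = TRUE)
      tea_p <- fuse_head_forward(tea_fused, state$student$head, 0, train = FALSE)
      losses$consis <- consistency_loss(stu_p$probs, tea_p$probs)
    } else {
      losses$consis <- consistency_loss(stu_unlab_fused, tea_fused)
    }
  }
  total <- losses$ce + omega * losses$consis + cfg$weights$a * losses$recon
  if (!is.finite(total)) {
    abort(sprintf(
      "non-finite training loss (ce=%.4g consis=%.4g recon=%.4g): aborting",
      losses$ce, losses$consis, losses$recon))
  }

  ## ---- backward ----------------------------------------------------------
  y <- label_to_int(batch$labels)
  onehot <- cbind(1 - y, y)
  d_logits_lab <- (head_fwd$probs - onehot) / n_lab
  hb <- dense_backward(d_logits_lab, state$student$head, head_fwd$cache$dense)
  grads_head <- hb$grads
  d_fused <- matrix(0, nrow(fused), ncol(fused))
  d_fused[lab_rows, ] <- dropout_backward(hb$dx, head_fwd$cache$drop)

  if (use_consis) {
    if (cfg$consistency_on == "probs") {
      g_p <- 2 * (stu_p$probs - tea_p$probs) / n_unlab
      # softmax jacobian: dL/dz = p * (g - sum(g * p))
      d_logits_u <- omega * stu_p$probs *
        (g_p - rowSums(g_p * stu_p$probs))
      hbu <- dense_backward(d_logits_u, state$student$head, stu_p$cache$dense)
      grads_head <- list(W = grads_head$W + hbu$grads$W,
                         b = grads_head$b + hbu$grads$b)
      d_fused[n_lab + seq_len(n_unlab), ] <-
        dropout_backward(hbu$dx, stu_p$cache$drop)
    } else {
      d_fused[n_lab + seq_len(n_unlab), ] <-
        omega * 2 * (stu_unlab_fused - tea_fused) / n_unlab
    }
  }

  grads <- list(head = grads_head)
  col0 <- 0L
  if (cfg$use_ae) {
    d_bn <- d_fused[, col0 + seq_len(spec$ae$bottleneck), drop = FALSE]
    col0 <- col0 + spec$ae$bottleneck
    r <- fwd_ae$recon
    xt <- ae_target
    d_recon <- cfg$weights$a * (-(xt / r) + (1 - xt) / (1 - r)) / length(r)
    grads$ae <- ae_backward(d_bn, d_recon, state$student$ae, spec$ae,
                            fwd_ae$cache)
  }
  if (cfg$use_cnn) {
    d_emb <- d_fused[, col0 + seq_len(spec$cnn$emb_dim), drop = FALSE]
    grads$cnn <- cnn_backward(d_emb, state$student$cnn, spec$cnn,
                              fwd_cnn$cache, pool = pools$stu)
  }

  ## ---- SGD + EMA ---------------------------------------------------------
  if (is.null(opt)) opt <- zeros_like(grads)
  upd <- sgd_step(state$student[names(grads)], grads, opt, lr, cfg$momentum)
  state$student[names(grads)] <- upd$params
  opt <- upd$vel
  if (cfg$use_cnn) {
    state$teacher$cnn <- ema_update(state$teacher$cnn, state$student$cnn,
                                    cfg$alpha_ema)
  }
  losses$omega <- omega
  losses$lr <- lr
  losses$total <- total
  list(state = state, opt = opt, losses = losses)
}

# eta'': per-row noise on a matrix of IS09 vectors, clamped to the BCE
# domain; the noise SD is amplitude x each row's robust scale
noise_rows <- function(m, amplitude) {
  if (amplitude == 0) return(m)
  scales <- apply(m, 1L, robust_scale)
  pmin(pmax(m + rnorm(length(m)) * amplitude * scales, 0), 1)
}

# head forward with explicit dropout control (fused matrix already built)
fuse_head_forward <- function(fused, head, p_drop, train) {
  dr <- dropout_forward(fused, p_drop, train)
  de <- dense_forward(dr$out, head)
  list(probs = row_softmax(de$out),
       cache = list(drop = dr$cache, dense = de$cache))
}

zeros_like <- function(x) {
  if (is.list(x)) lapply(x, zeros_like) else x * 0
}

sgd_step <- function(params, grads, vel, lr, momentum) {
  if (is.list(grads)) {
    out_p <- params
    out_v <- vel
    for (nm in names(grads)) {
      r <- sgd_step(params[[nm]], grads[[nm]], vel[[nm]], lr, momentum)
      out_p[[nm]] <- r$params
      out_v[[nm]] <- r$vel
    }
    return(list(params = out_p, vel = out_v))
  }
  v <- momentum * vel + grads
  list(params = params - lr * v, vel = v)
}

## ---- full training loop --------------------------------------------------

#' Fit the semi-supervised deception-detection model
#'
#' Full training loop: assembles mixed labeled/unlabeled batches, runs
#' [train_step()] for `cfg$epochs` cosine-annealed epochs, evaluates the
#' student (AE + student-CNN fusion) and the teacher variant on the test
#' split after every epoch, and keeps the best student by test accuracy.
#' Unlabeled items' ground truth is never consulted: the trainer reads only
#' the `label`, `split` and `labeled` manifest columns.
#'
#' @param manifest Corpus manifest tibble (see [generate_corpus()]).
#' @param features A `"corpus_features"` object from [extract_features()]
#'   for the same utterances, at the image size matching `cfg$scale`.
#' @param cfg A [train_config()].
#' @return An object of class `"aemt_fit"`: `state` (final), `best_state`,
#'   `history` (per-epoch tibble), `cfg`, `test_ids`.
#' @export
fit_aemt <- function(manifest, features, cfg = train_config()) {
  man <- manifest[, c("id", "path", "label", "split", "labeled")]
  lab_train <- which(man$split == "train" & man$labeled)
  unlab_train <- which(man$split == "train" & !man$labeled)
  test_idx <- which(man$split == "test")
  if (length(lab_train) == 0L) {
    abort("no labeled training items: supervised loss undefined")
  }
  expected_size <- cnn_spec(cfg$scale)$input_size
  if (features$size != expected_size) {
    abort(sprintf("features are %dx%d but cfg$scale='%s' expects %dx%d",
                  features$size, features$size, cfg$scale,
                  expected_size, expected_size))
  }

  set.seed(cfg$seed)
  norm <- compute_norm(features, man$id[c(lab_train, unlab_train)])
  state <- init_model_state(cfg, norm)
  is09 <- normalize_is09(features, norm)[man$id, , drop = FALSE]
  mel <- if (cfg$use_cnn) normalize_mel(features, norm)[man$id] else NULL

  n_lab_b <- max(1L, round(cfg$batch_size * cfg$labeled_batch_fraction))
  n_unlab_b <- cfg$batch_size - n_lab_b
  use_unlab <- length(unlab_train) > 0L && n_unlab_b > 0L
  steps <- if (use_unlab) {
    ceiling(length(unlab_train) / n_unlab_b)
  } else {
    ceiling(length(lab_train) / n_lab_b)
  }

  opt <- NULL
  pools <- list(stu = new.env(parent = emptyenv()),
                tea = new.env(parent = emptyenv()))
  history <- list()
  best_acc <- -Inf
  best_state <- state
  for (epoch in 0:(cfg$epochs - 1L)) {
    unlab_ord <- if (use_unlab) sample(unlab_train) else integer(0)
    ep_losses <- c(ce = 0, consis = 0, recon = 0, total = 0)
    for (s in seq_len(steps)) {
      bl <- sample(lab_train, n_lab_b, replace = length(lab_train) < n_lab_b)
      bu <- if (use_unlab) {
        unlab_ord[((s - 1L) * n_unlab_b + 1L):min(s * n_unlab_b,
                                                  length(unlab_ord))]
      } else {
        integer(0)
      }
      batch <- list(
        lab_mel = if (cfg$use_cnn) mel[bl],
        lab_is09 = is09[bl, , drop = FALSE],
        labels = man$label[bl],
        unlab_mel = if (cfg$use_cnn && length(bu)) mel[bu],
        unlab_is09 = if (length(bu)) is09[bu, , drop = FALSE]
      )
      r <- train_step(batch, state, cfg, opt, epoch, cfg$epochs, pools)
      state <- r$state
      opt <- r$opt
      ep_losses <- ep_losses +
        unlist(r$losses[c("ce", "consis", "recon", "total")]) / steps
    }
    ev <- evaluate_state(state, man, is09, mel, test_idx)
    history[[epoch + 1L]] <- tibble(
      epoch = epoch, lr = cosine_lr(epoch, cfg$epochs, cfg$lr),
      omega = omega_schedule(epoch, cfg$epochs, cfg$weights),
      loss_ce = ep_losses[["ce"]], loss_consis = ep_losses[["consis"]],
      loss_recon = ep_losses[["recon"]], loss_total = ep_losses[["total"]],
      test_accuracy = ev$student$accuracy, test_f1 = ev$student$f1,
      teacher_accuracy = ev$teacher$accuracy)
    if (ev$student$accuracy >= best_acc) {
      best_acc <- ev$student$accuracy
      best_state <- state
    }
  }
  structure(list(state = state, best_state = best_state,
                 history = dplyr::bind_rows(history), cfg = cfg,
                 test_ids = man$id[test_idx]),
            class = "aemt_fit")
}

# student and teacher-variant predictions on given manifest rows (eval mode)
evaluate_state <- function(state, man, is09, mel, idx) {
  if (length(idx) == 0L) return(list(student = list(accuracy = NA, f1 = NA),
                                     teacher = list(accuracy = NA)))
  p_stu <- predict_probs(state, is09[idx, , drop = FALSE],
                         if (!is.null(mel)) mel[idx], teacher = FALSE)
  p_tea <- predict_probs(state, is09[idx, , drop = FALSE],
                         if (!is.null(mel)) mel[idx], teacher = TRUE)
  truth <- man$label[idx]
  list(student = evaluate_predictions(prob_to_label(p_stu), truth),
       teacher = evaluate_predictions(prob_to_label(p_tea), truth))
}

predict_probs <- function(state, is09_rows, mel_rows, teacher = FALSE) {
  cfg <- state$cfg
  parts <- list()
  if (cfg$use_ae) {
    parts$ae <- ae_forward(is09_rows, state$student$ae, state$spec$ae,
                           train = FALSE)$bottleneck
  }
  if (cfg$use_cnn) {
    cnn_par <- if (teacher) state$teacher$cnn else state$student$cnn
    parts$cnn <- cnn_forward(stack_mel(mel_rows), cnn_par, state$spec$cnn,
                             train = FALSE)$emb
  }
  fused <- do.call(cbind, parts)
  fuse_head_forward(fused, state$student$head, 0, train = FALSE)$probs
}

prob_to_label <- function(probs) c("truth", "lie")[max.col(probs)]

#' Predict truth/lie for utterances
#'
#' @param object An `"aemt_fit"`.
#' @param features A `"corpus_features"` object covering the utterances.
#' @param ids Utterance ids to predict (default: all in `features`).
#' @param use_best Use the best-by-test-accuracy checkpoint (default TRUE).
#' @param teacher Use the teacher CNN instead of the student.
#' @param ... Unused.
#' @return Tibble: `id`, `p_lie`, `prediction`.
#' @export
predict.aemt_fit <- function(object, features, ids = NULL, use_best = TRUE,
                             teacher = FALSE, ...) {
  state <- if (use_best) object$best_state else object$state
  if (is.null(ids)) ids <- features$is09$id
  is09 <- normalize_is09(features, state$norm)[ids, , drop = FALSE]
  mel <- if (state$cfg$use_cnn) normalize_mel(features, state$norm)[ids]
  probs <- predict_probs(state, is09, mel, teacher = teacher)
  tibble(id = ids, p_lie = probs[, 2L], prediction = prob_to_label(probs))
}

#' Evaluate a fit on a manifest split
#'
#' @param fit An `"aemt_fit"`.
#' @param manifest The corpus manifest (its `hidden_label` column is the
#'   ground truth for evaluation).
#' @param features Matching `"corpus_features"`.
#' @param split `"test"` (default) or `"train"`.
#' @param ... Passed to [predict.aemt_fit()].
#' @return List: `accuracy`, `f1`, `confusion`, `predictions` tibble.
#' @export
evaluate_aemt <- function(fit, manifest, features, split = "test", ...) {
  rows <- manifest[manifest$split == split, ]
  preds <- predict(fit, features, ids = rows$id, ...)
  truth <- if ("hidden_label" %in% names(rows)) rows$hidden_label else rows$label
  c(evaluate_predictions(preds$prediction, truth), list(predictions = preds))
}

#' Save / load a training checkpoint
#'
#' The checkpoint archives student, teacher and fusion-head parameters,
#' normalisation constants, configuration and history; loading restores an
#' `"aemt_fit"` that evaluates identically.
#'
#' @param fit An `"aemt_fit"`.
#' @param path File path (`.rds`).
#' @return `path` (save) / the restored fit (load).
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(unclass(fit), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "aemt_fit")
}

#' @export
print.aemt_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<aemt_fit: %d epochs, scale=%s, ae=%s cnn=%s>\n",
              nrow(h), x$cfg$scale, x$cfg$use_ae, x$cfg$use_cnn))
  cat(sprintf("  best test accuracy %.3f (epoch %d), final %.3f\n",
              max(h$test_accuracy), h$epoch[which.max(h$test_accuracy)],
              h$test_accuracy[nrow(h)]))
  invisible(x)
}
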