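#' Student/teacher convolutional network specification
#'
#' The spectrogram branch: two blocks of three padded 3x3 convolutions
#' (BN + ReLU) separated by 2x2 max-pooling, then an unpadded 3x3
#' convolution followed by two padded ones, global average pooling over the
#' remaining spatial grid ("sum and average") to an embedding, and an
#' auxiliary fully connected 8-unit projection. At full scale the channel
#' widths are 32 / 64 / (128, 64, 32) on a 256x256x3 input, so the shape
#' sequence is 256-256-128-128-64-62-62-62 with a 32-dim embedding. The
#' desk scale keeps the identical topology on a 64x64x3 input with widths
#' 8 / 16 / (32, 16, 8), so it propagates shapes by the same rules while
#' running quickly on a CPU.
#'
#' @param scale `"full"` (256x256 input) or `"desk"` (64x64 input).
#' @return A list of class `"cnn_spec"`: `input_size`, `block1`, `block2`,
#'   `head` channel widths, `fc_out`, and the derived `layers` plan.
#' @export
cnn_spec <- function(scale = c("full", "desk")) {
  scale <- match.arg(scale)
  s <- if (scale == "full") {
    list(input_size = 256L, block1 = 32L, block2 = 64L,
         head = c(128L, 64L, 32L), fc_out = 8L)
  } else {
    list(input_size = 64L, block1 = 8L, block2 = 16L,
         head = c(32L, 16L, 8L), fc_out = 8L)
  }
  s$scale <- scale
  widths <- c(3L, rep(s$block1, 3L), rep(s$block2, 3L), s$head)
  pads <- c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 1L, 1L)
  layers <- list()
  ci <- 1L
  for (k in 1:9) {
    layers[[length(layers) + 1L]] <- list(type = "conv", name = paste0("c", k),
                                          c_in = widths[k], c_out = widths[k + 1L],
                                          pad = pads[k])
    layers[[length(layers) + 1L]] <- list(type = "bnrelu", name = paste0("bn", k),
                                          c = widths[k + 1L])
    if (k %in% c(3L, 6L)) layers[[length(layers) + 1L]] <- list(type = "pool")
  }
  s$layers <- layers
  s$emb_dim <- s$head[3L]
  structure(s, class = "cnn_spec")
}

#' Initialise CNN parameters (He-uniform convolutions)
#'
#' @param spec A [cnn_spec()].
#' @return Named list of parameter tensors (convolutions, batch-norm
#'   scales/offsets and running statistics, auxiliary projection).
#' @export
cnn_init <- function(spec) {
  p <- list()
  for (ly in spec$layers) {
    if (ly$type == "conv") p[[ly$name]] <- conv_init(ly$c_in, ly$c_out)
    if (ly$type == "bnrelu") p[[ly$name]] <- bn_init(ly$c)
  }
  p$fc <- dense_init(spec$emb_dim, spec$fc_out)
  p
}

#' CNN forward pass
#'
#' @param x `size x size x 3 x N` array (or `size x size x 3` for a single
#'   image) of 3D mel-spectrum inputs.
#' @param params Parameters from [cnn_init()].
#' @param spec The matching [cnn_spec()].
#' @param train Logical; training mode uses batch statistics in BN (and
#'   updates running statistics), eval mode uses running statistics.
#' @param keep_cache Keep layer caches for [cnn_backward()]; set FALSE for
#'   gradient-free forwards (the teacher, evaluation).
#' @param pool Optional environment used as a reusable buffer pool across
#'   steps of a training loop; NULL (the default) allocates fresh buffers.
#' @return List: `emb` (N x emb_dim pooled embedding), `aux` (N x 8
#'   projection), `params` (with updated BN statistics when `train`), and
#'   `cache` for [cnn_backward()].
#' @export
cnn_forward <- function(x, params, spec, train = FALSE, keep_cache = train,
                        pool = NULL) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1L] != spec$input_size || d[2L] != spec$input_size || d[3L] != 3L) {
    abort(sprintf("cnn input shape %s, expected %dx%dx3",
                  paste(d[1:3], collapse = "x"),
                  spec$input_size, spec$input_size))
  }
  h <- aperm(x, c(1L, 2L, 4L, 3L))            # (H, W, N, C) working layout
  hd <- dim(h)
  caches <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$type == "conv") {
      p <- params[[ly$name]]
      oh <- hd[1L] + 2L * ly$pad - 2L
      ow <- hd[2L] + 2L * ly$pad - 2L
      rows <- oh * ow * hd[3L]
      m <- buf_mat(pool, paste0("m_", ly$name), rows, 9L * hd[4L])
      im2col_pad_into(m, h, hd, ly$pad)
      w2 <- p$W
      dim(w2) <- c(9L * hd[4L], ly$c_out)
      h <- m %*% w2
      if (any(p$b != 0)) h <- h + rep(p$b, each = rows)
      if (keep_cache) caches[[i]] <- list(m = m, pad = ly$pad, in_dim = hd)
      hd <- c(oh, ow, hd[3L], ly$c_out)
    } else if (ly$type == "bnrelu") {
      p <- params[[ly$name]]
      n_sp <- prod(hd[1:3])
      if (train) {
        out <- buf_vec(pool, paste0("o_", ly$name), length(h))
        xhat <- if (keep_cache) {
          buf_vec(pool, paste0("h_", ly$name), length(h))
        } else {
          numeric(0)
        }
        st <- bn_relu_train_into(out, xhat, h, n_sp, p$gamma, p$beta,
                                 BN_EPS, keep_cache)
        p$run_mean <- BN_MOMENTUM * p$run_mean + (1 - BN_MOMENTUM) * st$mu
        p$run_var <- BN_MOMENTUM * p$run_var + (1 - BN_MOMENTUM) * st$var
        params[[ly$name]] <- p
        if (keep_cache) {
          caches[[i]] <- list(out = out, xhat = xhat, rstd = st$rstd,
                              gamma = p$gamma, dm = hd)
        }
        h <- out
      } else {
        hm <- matrix(h, n_sp, hd[4L])
        hm <- col_add(col_mul(col_sub(hm, p$run_mean),
                              p$gamma / sqrt(p$run_var + BN_EPS)), p$beta)
        h <- hm * (hm > 0)
      }
    } else {
      out <- buf_vec(pool, paste0("p_", i), length(h) %/% 4L)
      wh <- buf_int(pool, paste0("w_", i), length(h) %/% 4L)
      maxpool2_into(out, wh, h, hd)
      if (keep_cache) caches[[i]] <- list(wh = wh, in_dim = hd)
      h <- out
      hd <- c(hd[1L] %/% 2L, hd[2L] %/% 2L, hd[3L], hd[4L])
    }
  }
  emb <- matrix(colMeans(matrix(h, hd[1L] * hd[2L], hd[3L] * hd[4L])),
                hd[3L], hd[4L])
  fc <- dense_forward(emb, params$fc)
  list(emb = emb, aux = fc$out, params = params,
       cache = list(layers = caches, gap = hd, fc = fc$cache))
}

#' CNN backward pass
#'
#' @param d_emb N x emb_dim gradient of the loss w.r.t. the pooled
#'   embedding.
#' @param d_aux Optional N x 8 gradient w.r.t. the auxiliary projection.
#' @param params,spec,cache As produced by [cnn_forward()] in train mode.
#' @param pool Optional buffer pool (environment) shared with the matching
#'   [cnn_forward()] call.
#' @return List of gradients congruent with the (learnable) parameters.
#' @export
cnn_backward <- function(d_emb, params, spec, cache, d_aux = NULL,
                         pool = NULL) {
  grads <- list()
  if (!is.null(d_aux)) {
    r <- dense_backward(d_aux, params$fc, cache$fc)
    grads$fc <- r$grads
    d_emb <- d_emb + r$dx
  } else {
    grads$fc <- list(W = params$fc$W * 0, b = params$fc$b * 0)
  }
  hd <- cache$gap
  dh <- gap_backward(d_emb, hd)
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    cc <- cache$layers[[i]]
    if (ly$type == "conv") {
      p <- params[[ly$name]]
      rows <- nrow(cc$m)
      w2 <- p$W
      dim(w2) <- c(9L * cc$in_dim[4L], ly$c_out)
      need_dx <- i > 1L
      dcol <- if (need_dx) {
        buf_mat(pool, paste0("dc_", ly$name), rows, ncol(cc$m))
      } else {
        matrix(0, 0L, 0L)
      }
      g <- conv_bwd_gemms(cc$m, dh, w2, ly$c_out, dcol, need_dx)
      dim(g$W) <- dim(p$W)
      grads[[ly$name]] <- g
      if (need_dx) {
        dh <- buf_vec(pool, paste0("dx_", ly$name), prod(cc$in_dim))
        col2im_unpad_into(dh, dcol, cc$in_dim, cc$pad)
        hd <- cc$in_dim
      }
    } else if (ly$type == "bnrelu") {
      dx <- buf_vec(pool, paste0("do_", ly$name), length(dh))
      r <- bn_relu_backward_into(dx, dh, cc$out, cc$xhat, prod(cc$dm[1:3]),
                                 cc$gamma, cc$rstd)
      grads[[ly$name]] <- list(gamma = r$dgamma, beta = r$dbeta)
      dh <- dx
      hd <- cc$dm
    } else {
      dx <- buf_vec(pool, paste0("dp_", i), prod(cc$in_dim))
      maxpool2_backward_into(dx, dh, cc$wh, cc$in_dim)
      dh <- dx
      hd <- cc$in_dim
    }
  }
  grads
}

#' Shape trace of the convolutional network
#'
#' Propagates the input shape through every stage by the layer rules
#' (padded 3x3 keeps H and W; unpadded subtracts 2; 2x2 pooling halves;
#' pooling and averaging collapse the grid), reproducing the printed
#' layer table of the architecture.
#'
#' @param spec A [cnn_spec()].
#' @return Tibble with columns `layer`, `h`, `w`, `c`.
#' @export
cnn_shape_trace <- function(spec) {
  rows <- list(list(layer = "input", h = spec$input_size, w = spec$input_size, c = 3L))
  h <- spec$input_size
  k <- 0L
  for (ly in spec$layers) {
    if (ly$type == "conv") {
      k <- k + 1L
      if (ly$pad == 0L) h <- h - 2L
      rows[[length(rows) + 1L]] <-
        list(layer = paste0("conv", k, "+bn+relu"), h = h, w = h, c = ly$c_out)
    } else if (ly$type == "pool") {
      h <- h %/% 2L
      rows[[length(rows) + 1L]] <-
        list(layer = "max-pool", h = h, w = h, c = rows[[length(rows)]]$c)
    }
  }
  rows[[length(rows) + 1L]] <- list(layer = "global-average", h = 1L, w = 1L,
                                    c = spec$emb_dim)
  rows[[length(rows) + 1L]] <- list(layer = "full-connection", h = 1L, w = 1L,
                                    c = spec$fc_out)
  dplyr::bind_rows(lapply(rows, as_tibble))
}
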