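#' Autoencoder specification
#'
#' The acoustic-statistics branch: a dense bottleneck autoencoder on the
#' 384-dim IS09 vector. Encoder 384-256-128-64-32 (each layer linear + BN +
#' ELU, dropout after layer 4), decoder 32-128-180-256-384 (the asymmetric
#' 180-wide second layer is deliberate), terminal sigmoid so reconstructions
#' live in (0, 1) — the domain of the binary-cross-entropy reconstruction
#' loss — plus an auxiliary 32-to-8 projection head.
#'
#' Dropout sites: after encoder layer 4 (the bottleneck) and after decoder
#' layer 3. Dropout on the reconstruction itself would corrupt the loss
#' target, so the output layer is linear + sigmoid.
#'
#' @param input_dim Input width (default 384).
#' @return A list of class `"ae_spec"`.
#' @export
ae_spec <- function(input_dim = 384L) {
  structure(list(input_dim = as.integer(input_dim),
                 enc = c(256L, 128L, 64L, 32L),
                 dec = c(128L, 180L, 256L, as.integer(input_dim)),
                 bottleneck = 32L, proj_out = 8L),
            class = "ae_spec")
}

#' Initialise autoencoder parameters (Xavier-uniform)
#'
#' @param spec An [ae_spec()].
#' @return Named list of dense and batch-norm parameters.
#' @export
ae_init <- function(spec) {
  p <- list()
  dims_in <- c(spec$input_dim, spec$enc[1:3])
  for (i in 1:4) {
    p[[paste0("enc", i)]] <- dense_init(dims_in[i], spec$enc[i])
    p[[paste0("enc_bn", i)]] <- bn_init(spec$enc[i])
  }
  dims_in <- c(spec$bottleneck, spec$dec[1:3])
  for (i in 1:4) {
    p[[paste0("dec", i)]] <- dense_init(dims_in[i], spec$dec[i])
    if (i < 4L) p[[paste0("dec_bn", i)]] <- bn_init(spec$dec[i])
  }
  p$proj <- dense_init(spec$bottleneck, spec$proj_out)
  p
}

#' Autoencoder forward pass
#'
#' @param x N x 384 matrix of min-max-normalized IS09 vectors (entries in
#'   `[0, 1]`), or a single length-384 vector.
#' @param params Parameters from [ae_init()].
#' @param spec The matching [ae_spec()].
#' @param train Logical training mode (BN batch statistics, dropout on).
#' @param p_drop Dropout probability at the two dropout sites.
#' @return List: `bottleneck` (N x 32), `recon` (N x 384, entries in
#'   (0, 1)), `aux` (N x 8), `params`, `cache`.
#' @export
ae_forward <- function(x, params, spec, train = FALSE, p_drop = 0) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != spec$input_dim) {
    abort(sprintf("ae input width %d, expected %d", ncol(x), spec$input_dim))
  }
  cache <- list()
  h <- x
  for (i in 1:4) {
    de <- dense_forward(h, params[[paste0("enc", i)]])
    bn <- bn_forward_mat(de$out, params[[paste0("enc_bn", i)]], train)
    params[[paste0("enc_bn", i)]] <- bn$params
    ac <- elu_forward(bn$out)
    cache[[paste0("enc", i)]] <- list(dense = de$cache, bn = bn$cache, elu = ac$cache)
    h <- ac$out
  }
  dr <- dropout_forward(h, p_drop, train)
  cache$drop_bottleneck <- dr$cache
  bottleneck <- dr$out

  h <- bottleneck
  for (i in 1:3) {
    de <- dense_forward(h, params[[paste0("dec", i)]])
    bn <- bn_forward_mat(de$out, params[[paste0("dec_bn", i)]], train)
    params[[paste0("dec_bn", i)]] <- bn$params
    ac <- elu_forward(bn$out)
    cache[[paste0("dec", i)]] <- list(dense = de$cache, bn = bn$cache, elu = ac$cache)
    h <- ac$out
  }
  dr2 <- dropout_forward(h, p_drop, train)
  cache$drop_decoder <- dr2$cache
  de4 <- dense_forward(dr2$out, params$dec4)
  sg <- sigmoid_forward(de4$out)
  cache$dec4 <- list(dense = de4$cache, sigmoid = sg$cache)

  pj <- dense_forward(bottleneck, params$proj)
  cache$proj <- pj$cache
  list(bottleneck = bottleneck, recon = sg$out, aux = pj$out,
       params = params, cache = cache)
}

#' Autoencoder backward pass
#'
#' @param d_bottleneck N x 32 gradient w.r.t. the bottleneck (from the
#'   classifier/consistency path); may be zero.
#' @param d_recon N x 384 gradient w.r.t. the reconstruction output.
#' @param params,spec,cache From [ae_forward()] in train mode.
#' @param d_aux Optional N x 8 gradient w.r.t. the projection head.
#' @return List of gradients congruent with the learnable parameters.
#' @export
ae_backward <- function(d_bottleneck, d_recon, params, spec, cache, d_aux = NULL) {
  grads <- list()
  ## decoder
  dz <- sigmoid_backward(d_recon, cache$dec4$sigmoid)
  r <- dense_backward(dz, params$dec4, cache$dec4$dense)
  grads$dec4 <- r$grads
  dh <- dropout_backward(r$dx, cache$drop_decoder)
  for (i in 3:1) {
    cc <- cache[[paste0("dec", i)]]
    dh <- elu_backward(dh, cc$elu)
    bb <- bn_backward_mat(dh, cc$bn)
    grads[[paste0("dec_bn", i)]] <- bb$grads
    r <- dense_backward(bb$dx, params[[paste0("dec", i)]], cc$dense)
    grads[[paste0("dec", i)]] <- r$grads
    dh <- r$dx
  }
  d_bn <- d_bottleneck + dh
  if (!is.null(d_aux)) {
    r <- dense_backward(d_aux, params$proj, cache$proj)
    grads$proj <- r$grads
    d_bn <- d_bn + r$dx
  } else {
    grads$proj <- list(W = params$proj$W * 0, b = params$proj$b * 0)
  }
  ## encoder
  dh <- dropout_backward(d_bn, cache$drop_bottleneck)
  for (i in 4:1) {
    cc <- cache[[paste0("enc", i)]]
    dh <- elu_backward(dh, cc$elu)
    bb <- bn_backward_mat(dh, cc$bn)
    grads[[paste0("enc_bn", i)]] <- bb$grads
    r <- dense_backward(bb$dx, params[[paste0("enc", i)]], cc$dense)
    grads[[paste0("enc", i)]] <- r$grads
    dh <- r$dx
  }
  grads
}
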