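# Neural-network primitives. Convolutional activations are (H, W, N, C)
# arrays, column-major with the channel last, so every layer reduces to a
# BLAS matrix product over an (H*W*N) x C view; the heavy kernels
# (im2col/col2im, fused BN+ReLU, pooling, backward GEMMs) live in
# src/pooled.cpp and write into reusable buffers.

## ---- initialisers --------------------------------------------------------

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dims), -lim, lim), dims)
}

xavier_uniform <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

conv_init <- function(c_in, c_out, k = 3L) {
  list(W = he_uniform(c(k, k, c_in, c_out), fan_in = k * k * c_in),
       b = numeric(c_out))
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c))
}

dense_init <- function(n_in, n_out) {
  list(W = xavier_uniform(n_in, n_out), b = numeric(n_out))
}



## ---- batch normalisation (matrix form, channel = column) -----------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# column-broadcast helpers: `v` has one entry per column of `xm`
col_mul <- function(xm, v) xm * rep(v, each = nrow(xm))
col_sub <- function(xm, v) xm - rep(v, each = nrow(xm))
col_add <- function(xm, v) xm + rep(v, each = nrow(xm))

bn_forward_mat <- function(xm, p, train) {
  if (train) {
    mu <- colMeans(xm)
    xc <- col_sub(xm, mu)
    v <- colMeans(xc^2)
    rstd <- 1 / sqrt(v + BN_EPS)
    xhat <- col_mul(xc, rstd)
    p$run_mean <- BN_MOMENTUM * p$run_mean + (1 - BN_MOMENTUM) * mu
    p$run_var <- BN_MOMENTUM * p$run_var + (1 - BN_MOMENTUM) * v
    cache <- list(xhat = xhat, rstd = rstd, gamma = p$gamma)
  } else {
    xhat <- col_mul(col_sub(xm, p$run_mean), 1 / sqrt(p$run_var + BN_EPS))
    cache <- NULL
  }
  out <- col_add(col_mul(xhat, p$gamma), p$beta)
  list(out = out, cache = cache, params = p)
}

bn_backward_mat <- function(dout, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- col_mul(dout, cache$gamma)
  t1 <- col_sub(dxhat, colMeans(dxhat))
  t2 <- col_mul(xhat, colMeans(dxhat * xhat))
  dx <- col_mul(t1 - t2, cache$rstd)
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# spatial BN over (H, W, N) per channel: reshape to (H*W*N) x C


## ---- activations ---------------------------------------------------------


elu_forward <- function(x, alpha = 1) {
  neg <- x <= 0
  out <- x
  out[neg] <- alpha * (exp(x[neg]) - 1)
  list(out = out, cache = list(neg = neg, out_neg = out, alpha = alpha))
}

elu_backward <- function(dout, cache) {
  # d/dx elu = 1 (x > 0), elu(x) + alpha (x <= 0)
  g <- dout
  g[cache$neg] <- dout[cache$neg] * (cache$out_neg[cache$neg] + cache$alpha)
  g
}

sigmoid_forward <- function(x) {
  out <- 1 / (1 + exp(-x))
  # keep strictly inside (0, 1): the BCE reconstruction loss needs log(out)
  out <- pmin(pmax(out, 1e-12), 1 - 1e-12)
  list(out = out, cache = out)
}

sigmoid_backward <- function(dout, out) dout * out * (1 - out)

# backward of global average pooling over the spatial grid
gap_backward <- function(dout, in_dim) {
  array(rep(as.vector(dout) / (in_dim[1L] * in_dim[2L]),
            each = in_dim[1L] * in_dim[2L]), in_dim)
}

## ---- dense / dropout -----------------------------------------------------

dense_forward <- function(xm, p) {
  list(out = col_add(xm %*% p$W, p$b), cache = xm)
}

dense_backward <- function(dout, p, xm) {
  list(dx = dout %*% t(p$W),
       grads = list(W = crossprod(xm, dout), b = colSums(dout)))
}

# inverted dropout; `p_drop` is the probability of zeroing a unit
dropout_forward <- function(x, p_drop, train) {
  if (!train || p_drop <= 0) return(list(out = x, cache = NULL))
  stopifnot(p_drop < 1)
  mask <- array((runif(length(x)) >= p_drop) / (1 - p_drop), dim(x) %||% length(x))
  list(out = x * mask, cache = mask)
}

dropout_backward <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a

row_softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## ---- buffer pool ---------------------------------------------------------
# Reusable numeric buffers for the training loop. Pooled buffers are written
# in place by the C++ kernels (the only writers); a NULL pool falls back to
# fresh allocations, which is what the gradient-check and evaluation paths
# use. Pools are private to one fit and reset at its start.

buf_mat <- function(pool, key, r, c) {
  if (is.null(pool)) return(matrix(0, r, c))
  b <- pool[[key]]
  if (is.null(b) || nrow(b) != r || ncol(b) != c) {
    b <- matrix(0, r, c)
    pool[[key]] <- b
  }
  b
}

buf_vec <- function(pool, key, n) {
  if (is.null(pool)) return(numeric(n))
  b <- pool[[key]]
  if (is.null(b) || length(b) != n) {
    b <- numeric(n)
    pool[[key]] <- b
  }
  b
}

buf_int <- function(pool, key, n) {
  if (is.null(pool)) return(integer(n))
  b <- pool[[key]]
  if (is.null(b) || length(b) != n) {
    b <- integer(n)
    pool[[key]] <- b
  }
  b
}
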