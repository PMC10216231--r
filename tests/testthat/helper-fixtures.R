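# Shared fixtures, built in code and memoised for the session.
# Heavy objects (the desk-scale benchmark corpus and its features) are
# created once and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a 1 s 48 kHz test tone
tone_wav <- function(freq = 1000, dur = 1, fs = 48000L, amp = 0.5) {
  waveform(amp * sin(2 * pi * freq * seq(0, dur, by = 1 / fs)[-1]), fs)
}

# tiny corpus on disk: 12 utterances, short durations (fast to synthesize)
small_corpus <- function() {
  fixture("small_corpus", function() {
    dir <- file.path(tempdir(), "deceptr-small-corpus")
    cfg <- synth_config(n_utterances = 12L, n_labeled = 8L,
                        duration_s = c(1, 2), class_separation = 2.5,
                        seed = 401L)
    manifest <- generate_corpus(cfg, dir)
    list(cfg = cfg, dir = dir, manifest = manifest)
  })
}

# the desk-scale benchmark: 120 utterances at the generator's default
# durations, separation 2.5, 30% of training items labeled
bench_corpus <- function() {
  fixture("bench_corpus", function() {
    dir <- file.path(tempdir(), "deceptr-bench-corpus")
    cfg <- synth_config(n_utterances = 120L, n_labeled = 36L,
                        class_separation = 2.5, seed = 11L)
    manifest <- generate_corpus(cfg, dir)
    list(cfg = cfg, dir = dir, manifest = manifest)
  })
}

bench_features <- function() {
  fixture("bench_features", function() {
    extract_features(bench_corpus()$manifest, size = 64L)
  })
}

# quick IS09-style feature summaries for generator-statistics tests: mean F0
# column over a batch of synthesized utterances of one class
f0_mean_draws <- function(n, class_label, separation, seed) {
  cfg <- synth_config(duration_s = c(1, 2), class_separation = separation,
                      seed = seed)
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    llds <- extract_llds(synthesize_utterance(class_label, cfg))
    mean(llds[, "f0"])
  }, numeric(1))
}

# brute-force reference for the 12 functionals, written independently of
# apply_functionals(): plain textbook formulas, no shared code
brute_functionals <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  tt <- (0:(n - 1)) / (n - 1)
  b <- sum((tt - mean(tt)) * (x - mu)) / sum((tt - mean(tt))^2)
  a <- mu - b * mean(tt)
  res <- x - a - b * tt
  c(mu,
    sqrt(sum((x - mu)^2) / (n - 1)),
    if (m2 > 0) m4 / m2^2 - 3 else 0,
    if (m2 > 0) m3 / m2^1.5 else 0,
    max(x), min(x),
    (which.max(x) - 1) / (n - 1),
    (which.min(x) - 1) / (n - 1),
    max(x) - min(x), a, b, sum(res^2) / n)
}

# tiny-network finite-difference gradient checker used by the loss and
# acceptance suites; builds a miniature two-branch model and compares
# backpropagated gradients of the combined loss with central differences
tiny_model <- function(seed = 5L) {
  set.seed(seed)
  spec_cnn <- cnn_spec("desk")
  spec_cnn$input_size <- 16L
  spec_cnn$layers <- lapply(spec_cnn$layers, function(ly) {
    if (!is.null(ly$c_in)) {
      ly$c_in <- max(2L, ly$c_in %/% 4L)
      ly$c_out <- max(2L, ly$c_out %/% 4L)
      if (ly$name == "c1") ly$c_in <- 3L
    }
    if (!is.null(ly$c)) ly$c <- max(2L, ly$c %/% 4L)
    ly
  })
  convs <- Filter(function(ly) ly$type == "conv", spec_cnn$layers)
  spec_cnn$emb_dim <- convs[[length(convs)]]$c_out
  spec_ae <- ae_spec(12L)
  spec_ae$enc <- c(10L, 8L, 6L, 4L)
  spec_ae$dec <- c(6L, 7L, 9L, 12L)
  spec_ae$bottleneck <- 4L
  params <- list(cnn = cnn_init(spec_cnn), ae = ae_init(spec_ae),
                 head = fusion_init(spec_cnn$emb_dim + 4L))
  n <- 3L
  list(spec_cnn = spec_cnn, spec_ae = spec_ae, params = params,
       x_cnn = array(rnorm(16 * 16 * 3 * n), c(16L, 16L, 3L, n)),
       x_ae = matrix(runif(n * 12L), n, 12L),
       y = c(1L, 0L, 1L),
       tea = matrix(rnorm(n * (spec_cnn$emb_dim + 4L)),
                    n, spec_cnn$emb_dim + 4L))
}

# total loss (ce + 0.7 * consis + 0.5 * recon) of the tiny model as a pure
# function of its parameters; deterministic (no dropout, fixed inputs)
tiny_loss <- function(m, params) {
  fc <- cnn_forward(m$x_cnn, params$cnn, m$spec_cnn, train = TRUE)
  fa <- ae_forward(m$x_ae, params$ae, m$spec_ae, train = TRUE, p_drop = 0)
  fused <- cbind(fa$bottleneck, fc$emb)
  hf <- fuse_head_forward(fused, params$head, 0, train = FALSE)
  ce <- supervised_loss(hf$probs, m$y)
  consis <- consistency_loss(fused, m$tea)
  recon <- reconstruction_loss(m$x_ae, fa$recon)
  list(total = ce + 0.7 * consis + 0.5 * recon,
       fc = fc, fa = fa, fused = fused, hf = hf)
}

# analytic gradients of tiny_loss w.r.t. all parameters
tiny_grads <- function(m, params) {
  r <- tiny_loss(m, params)
  n <- length(m$y)
  onehot <- cbind(1 - m$y, m$y)
  d_logits <- (r$hf$probs - onehot) / n
  hb <- dense_backward(d_logits, params$head, r$hf$cache$dense)
  d_fused <- hb$dx + 0.7 * 2 * (r$fused - m$tea) / n
  d_bn <- d_fused[, 1:4, drop = FALSE]
  d_emb <- d_fused[, -(1:4), drop = FALSE]
  rec <- r$fa$recon
  d_recon <- 0.5 * (-(m$x_ae / rec) + (1 - m$x_ae) / (1 - rec)) / length(rec)
  list(head = hb$grads,
       ae = ae_backward(d_bn, d_recon, params$ae, m$spec_ae, r$fa$cache),
       cnn = cnn_backward(d_emb, params$cnn, m$spec_cnn, r$fc$cache),
       loss = r$total)
}

# central finite difference of tiny_loss w.r.t. one scalar parameter
tiny_fd <- function(m, params, path, idx, eps = 1e-5) {
  pp <- params
  pp[[path]][idx] <- pp[[path]][idx] + eps
  up <- tiny_loss(m, pp)$total
  pp[[path]][idx] <- pp[[path]][idx] - 2 * eps
  dn <- tiny_loss(m, pp)$total
  (up - dn) / (2 * eps)
}

# one synthesized utterance at a fixed seed (truth class, short duration)
synthesize_once <- function(seed = 1L, class_label = "truth", separation = 2) {
  set.seed(seed)
  synthesize_utterance(class_label,
                       synth_config(duration_s = c(1, 1.5),
                                    class_separation = separation,
                                    seed = seed))
}
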