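#' Synthetic corpus configuration
#'
#' Parameters of the synthetic truth/lie speech corpus generator. The
#' generator emulates the statistical shape of a werewolf-game deception
#' corpus: ~1,103 utterances of a few seconds each at 48 kHz, two classes
#' whose acoustic statistics differ — the deceptive class has an elevated
#' mean fundamental frequency, more variable energy dynamics, and a higher
#' pause rate — plus a labeled subset of configurable size.
#'
#' `class_separation` scales all three between-class shifts; 0 makes the
#' classes statistically identical. Per separation unit the deceptive class
#' gains +10 Hz mean F0 (against an 6 Hz between-speaker SD), +0.08 on the
#' log-energy modulation SD, and +1.5 percentage points of pause time.
#'
#' @param n_utterances Corpus size (default 1103).
#' @param deception_fraction Fraction of deceptive utterances (default
#'   521/1103).
#' @param n_labeled Number of labeled training utterances.
#' @param duration_s Length-2 range of utterance durations in seconds.
#' @param sample_rate Hz (default 48000).
#' @param class_separation Effect-size multiplier (>= 0).
#' @param noise_level Additive background-noise amplitude.
#' @param seed Integer RNG seed.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_utterances = 1103L,
                         deception_fraction = 521 / 1103,
                         n_labeled = 600L,
                         duration_s = c(2, 8),
                         sample_rate = 48000L,
                         class_separation = 1,
                         noise_level = 0.01,
                         seed = 1L) {
  stopifnot(deception_fraction > 0, deception_fraction < 1,
            n_labeled <= n_utterances, class_separation >= 0,
            length(duration_s) == 2L, duration_s[1] > 0.1)
  structure(list(n_utterances = as.integer(n_utterances),
                 deception_fraction = deception_fraction,
                 n_labeled = as.integer(n_labeled),
                 duration_s = duration_s,
                 sample_rate = as.integer(sample_rate),
                 class_separation = class_separation,
                 noise_level = noise_level,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# class-conditional generative parameters; the deceptive class is shifted by
# class_separation along F0 mean, energy-modulation SD and pause rate
class_params <- function(label, sep) {
  lie <- label == "lie"
  list(
    f0_mean   = 115 + if (lie) 10 * sep else 0,   # Hz, speaker draw SD 6
    f0_sd     = 6,
    energy_sd = 0.30 + if (lie) 0.08 * sep else 0,
    pause_frac = min(0.45, 0.12 + if (lie) 0.015 * sep else 0)
  )
}

#' Synthesize one utterance
#'
#' Produces a voiced-speech-like proxy signal: a sawtooth glottal source
#' with a slowly drifting, jittered F0 contour, three formant-like
#' two-pole resonators (with per-utterance speaker variation), slow
#' log-normal energy modulation, pause gating, and additive Gaussian
#' background noise. The deceptive class draws its F0 mean, energy
#' modulation SD and pause rate from distributions shifted by
#' `cfg$class_separation`. Draws from the current RNG stream: seed the
#' session (or use [generate_corpus()]) for reproducibility.
#'
#' @param class_label `"truth"` or `"lie"`.
#' @param cfg A [synth_config()].
#' @return A [waveform()].
#' @export
synthesize_utterance <- function(class_label, cfg) {
  stopifnot(class_label %in% c("truth", "lie"))
  fs <- cfg$sample_rate
  dur <- runif(1, cfg$duration_s[1], cfg$duration_s[2])
  n <- round(dur * fs)
  p <- class_params(class_label, cfg$class_separation)

  ## F0 contour: speaker mean + slow drift + cycle jitter
  f0_base <- rnorm(1, p$f0_mean, p$f0_sd)
  drift <- smooth_noise(n, fs, cutoff_hz = 2) * 0.06 * f0_base
  jitter <- smooth_noise(n, fs, cutoff_hz = 30) * 0.01 * f0_base
  f0 <- pmax(60, f0_base + drift + jitter)
  phase <- cumsum(f0 / fs)
  src <- 2 * (phase %% 1) - 1                       # sawtooth: all harmonics

  ## formant-like resonators with per-utterance speaker variation
  formants <- c(600, 1700, 2700) * exp(rnorm(3, 0, 0.05))
  bws <- c(90, 130, 180)
  y <- src
  for (k in 1:3) {
    rr <- exp(-pi * bws[k] / fs)
    a1 <- 2 * rr * cos(2 * pi * formants[k] / fs)
    a2 <- -rr^2
    y <- as.numeric(filter(y, c(a1, a2), method = "recursive"))
  }

  ## slow energy modulation (log-normal), class-dependent variance
  env <- exp(p$energy_sd * smooth_noise(n, fs, cutoff_hz = 3))
  y <- y * env

  ## pause gating: alternating speech bursts and silences
  gate <- pause_gate(n, fs, p$pause_frac)
  y <- y * gate

  y <- y / max(abs(y), 1e-8) * 0.5
  y <- y + rnorm(n, 0, cfg$noise_level)
  waveform(pmax(pmin(y, 1), -1), fs)
}

# slowly varying unit-variance Gaussian noise: drawn at ~4 x cutoff_hz and
# linearly interpolated up to the audio rate (cheap band-limiting)
smooth_noise <- function(n, fs, cutoff_hz) {
  n_ctrl <- max(4L, ceiling(n / fs * cutoff_hz * 4))
  e <- rnorm(n_ctrl)
  s <- approx(seq(0, 1, length.out = n_ctrl), e,
              xout = seq(0, 1, length.out = n))$y
  s / (sd(s) + 1e-12)
}

# binary speech/pause gate with 10 ms cosine ramps
pause_gate <- function(n, fs, pause_frac) {
  gate <- numeric(n)
  pos <- 1L
  speaking <- TRUE
  mean_speech <- 0.8 * fs
  mean_pause <- max(0.05 * fs, pause_frac / max(1 - pause_frac, 0.05) * mean_speech)
  while (pos <= n) {
    len <- if (speaking) {
      round(mean_speech * exp(rnorm(1, 0, 0.3)))
    } else {
      round(mean_pause * exp(rnorm(1, 0, 0.3)))
    }
    len <- max(len, round(0.05 * fs))
    end <- min(n, pos + len - 1L)
    gate[pos:end] <- if (speaking) 1 else 0
    pos <- end + 1L
    speaking <- !speaking
  }
  ramp <- round(0.010 * fs)
  kern <- rep(1 / ramp, ramp)
  sm <- as.numeric(filter(gate, kern, sides = 2L))
  sm[is.na(sm)] <- gate[is.na(sm)]
  sm
}

#' Generate a synthetic truth/lie corpus
#'
#' Draws class labels to match `deception_fraction` (rounded count of
#' deceptive utterances), synthesizes every utterance, writes 16-bit WAV
#' files under `dir`, assigns a 9:1 stratified train/test split, marks a
#' stratified random labeled subset of `n_labeled` training utterances, and
#' writes `manifest.csv` plus a YAML copy of the configuration. Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory.
#' @param train_ratio Train fraction of the 9:1 split (default 0.9).
#' @return The manifest tibble: columns `id`, `path`, `label` (NA for
#'   unlabeled training items), `hidden_label` (ground truth, for post-hoc
#'   evaluation only), `split`, `labeled`.
#' @export
generate_corpus <- function(cfg, dir, train_ratio = 0.9) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  n <- cfg$n_utterances
  n_lie <- round(n * cfg$deception_fraction)
  labels <- sample(c(rep("lie", n_lie), rep("truth", n - n_lie)))
  ids <- sprintf("utt%04d", seq_len(n))
  paths <- file.path(dir, paste0(ids, ".wav"))
  for (i in seq_len(n)) {
    write_wav(synthesize_utterance(labels[i], cfg), paths[i])
  }
  manifest <- tibble(id = ids, path = paths, label = labels,
                     hidden_label = labels,
                     split = NA_character_, labeled = TRUE)
  manifest <- split_train_test(manifest, train_ratio = train_ratio,
                               seed = cfg$seed + 1L)
  ## choose the labeled subset: stratified random among training items
  tr_idx <- which(manifest$split == "train")
  set.seed(cfg$seed + 2L)
  lab_idx <- stratified_sample(tr_idx, manifest$hidden_label[tr_idx],
                               min(cfg$n_labeled, length(tr_idx)))
  manifest$labeled <- FALSE
  manifest$labeled[lab_idx] <- TRUE
  manifest$labeled[manifest$split == "test"] <- TRUE   # test items keep labels
  manifest$label[!manifest$labeled] <- NA_character_
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  manifest
}

stratified_sample <- function(idx, strata, n_take) {
  take <- integer(0)
  tab <- table(strata)
  alloc <- round(n_take * tab / sum(tab))
  # fix rounding so the total is exact
  while (sum(alloc) > n_take) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_take) alloc[which.min(alloc)] <- alloc[which.min(alloc)] + 1L
  for (s in names(tab)) {
    pool <- idx[strata == s]
    take <- c(take, sample(pool, min(alloc[[s]], length(pool))))
  }
  sort(take)
}

#' Stratified train/test split
#'
#' Splits a manifest into train and test with `floor(train_ratio * N)`
#' training items (so 1,103 utterances at 0.9 give exactly 992/111),
#' stratified by class via a seeded permutation.
#'
#' @param manifest Manifest tibble with a `hidden_label` (or `label`) column.
#' @param train_ratio Train fraction in (0, 1).
#' @param seed Integer seed for the permutation.
#' @return The manifest with its `split` column filled in.
#' @export
split_train_test <- function(manifest, train_ratio = 0.9, seed = 1L) {
  stopifnot(train_ratio > 0, train_ratio < 1)
  n <- nrow(manifest)
  if (n < 2L) abort("need at least 2 utterances to split")
  strata <- if ("hidden_label" %in% names(manifest)) manifest$hidden_label else manifest$label
  n_train <- floor(train_ratio * n)
  set.seed(seed)
  ord <- sample.int(n)                      # seeded permutation
  # allocate test per stratum proportionally, walking the permutation
  n_test <- n - n_train
  test_alloc <- round(n_test * table(strata) / n)
  while (sum(test_alloc) > n_test) test_alloc[which.max(test_alloc)] <- test_alloc[which.max(test_alloc)] - 1L
  while (sum(test_alloc) < n_test) test_alloc[which.min(test_alloc)] <- test_alloc[which.min(test_alloc)] + 1L
  split <- rep("train", n)
  for (s in names(test_alloc)) {
    pool <- ord[strata[ord] == s]
    split[head(pool, test_alloc[[s]])] <- "test"
  }
  manifest$split <- split
  manifest
}

#' Read a corpus manifest written by [generate_corpus()]
#'
#' @param path Path to `manifest.csv` or its directory.
#' @return The manifest tibble.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  readr::read_csv(path, show_col_types = FALSE)
}
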