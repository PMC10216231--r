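#' The twelve utterance-level functionals
#'
#' Collapses one per-frame descriptor trajectory into the 12 statistics of
#' the Interspeech-2009 feature set, in fixed order: mean, stddev, kurtosis,
#' skewness, max, min, maxposition, minposition, range, offset, slope, MSE.
#'
#' Definitions: stddev is the sample standard deviation; skewness is
#' `m3 / m2^1.5` and kurtosis the excess `m4 / m2^2 - 3` (both 0 for a
#' constant series); max/min positions are the relative index of the first
#' extremum, `(which - 1) / (T - 1)` in `[0, 1]`; offset and slope are the
#' intercept and slope of the least-squares line over normalized time
#' `t = (0, ..., 1)`, and MSE is that regression's mean squared residual.
#'
#' @param series Numeric vector, length >= 2.
#' @return Named numeric vector of length 12.
#' @examples
#' apply_functionals(c(0, 1, 2, 3))  # slope 3, offset 0, MSE 0
#' @export
apply_functionals <- function(series) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 2L) abort("series must have length >= 2 (slope undefined otherwise)")
  mu <- mean(x)
  xc <- x - mu
  m2 <- mean(xc^2)
  sd_x <- sd(x)
  if (m2 > 0) {
    skew <- mean(xc^3) / m2^1.5
    kurt <- mean(xc^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  i_max <- which.max(x)
  i_min <- which.min(x)
  tt <- (seq_len(n) - 1L) / (n - 1L)
  t_c <- tt - mean(tt)
  slope <- sum(t_c * xc) / sum(t_c^2)
  offset <- mu - slope * mean(tt)
  resid <- x - (offset + slope * tt)
  c(mean = mu, stddev = sd_x, kurtosis = kurt, skewness = skew,
    max = max(x), min = min(x),
    maxposition = (i_max - 1L) / (n - 1L),
    minposition = (i_min - 1L) / (n - 1L),
    range = max(x) - min(x), offset = offset, slope = slope,
    mse = mean(resid^2))
}

functional_names <- c("mean", "stddev", "kurtosis", "skewness", "max", "min",
                      "maxposition", "minposition", "range", "offset",
                      "slope", "mse")

#' IS09 acoustic statistics vector
#'
#' The full Interspeech-2009 emotion challenge feature vector: the 16
#' low-level descriptors of [extract_llds()] and their first-order
#' regression deltas, each summarised by the 12 functionals of
#' [apply_functionals()] — `16 x 2 x 12 = 384` features. Layout: for each
#' descriptor, the 12 functionals of the raw trajectory followed by the 12
#' functionals of its delta.
#'
#' @param wav A [waveform()].
#' @param ... Passed to [extract_llds()].
#' @return Named numeric vector of length 384.
#' @export
extract_is09 <- function(wav, ...) {
  llds <- extract_llds(wav, ...)
  deltas <- compute_delta(llds, 1L)
  out <- numeric(0)
  nm <- character(0)
  for (k in seq_len(ncol(llds))) {
    f_raw <- apply_functionals(llds[, k])
    f_del <- apply_functionals(deltas[, k])
    out <- c(out, f_raw, f_del)
    nm <- c(nm,
            paste0(colnames(llds)[k], "_", functional_names),
            paste0(colnames(llds)[k], "_de_", functional_names))
  }
  names(out) <- nm
  out
}

#' Extract both feature views for a whole corpus
#'
#' Runs the IS09 and 3D mel-spectrum extractors over every utterance of a
#' manifest and returns them together: a feature table (one row per
#' utterance, 384 feature columns) and a list of `size x size x 3` mel
#' tensors, aligned by `id`.
#'
#' @param manifest A corpus manifest tibble (see [generate_corpus()]), with
#'   columns `id` and `path`.
#' @param size Side length of the mel-spectrum image (256 full scale, 64
#'   desk scale).
#' @param what `"both"` (default) or `"is09"` to skip the mel tensors (for
#'   feature-table-only analyses such as the linear probe).
#' @param verbose Print progress every 25 utterances.
#' @return A list of class `"corpus_features"`: `is09` (tibble: `id` +
#'   384 columns), `mel` (named list of arrays; empty for `what = "is09"`),
#'   `size`, `params`.
#' @export
extract_features <- function(manifest, size = 64L, what = c("both", "is09"),
                             verbose = FALSE) {
  stopifnot(all(c("id", "path") %in% names(manifest)))
  what <- match.arg(what)
  ids <- manifest$id
  mel <- vector("list", length(ids))
  names(mel) <- ids
  is09 <- matrix(NA_real_, length(ids), 384L)
  for (i in seq_along(ids)) {
    wav <- read_wav(manifest$path[i])
    if (what == "both") mel[[i]] <- build_melspec3d(wav, size = size)
    v <- extract_is09(wav)
    if (i == 1L) colnames(is09) <- names(v)
    is09[i, ] <- v
    if (verbose && i %% 25L == 0L) message(sprintf("  extracted %d/%d", i, length(ids)))
  }
  structure(list(
    is09 = dplyr::bind_cols(tibble(id = ids), as_tibble(is09)),
    mel = mel,
    size = as.integer(size),
    params = list(n_mels = 64L, win_ms = 25, hop_ms = 10, size = as.integer(size))
  ), class = "corpus_features")
}

#' @export
print.corpus_features <- function(x, ...) {
  cat(sprintf("<corpus_features: %d utterances, IS09 384-dim, mel %dx%dx3>\n",
              nrow(x$is09), x$size, x$size))
  invisible(x)
}

#' Write / read a feature cache
#'
#' The IS09 table is stored as CSV; mel tensors as a flat little-endian
#' float64 binary alongside a JSON sidecar recording ids, tensor shape and
#' extraction parameters.
#'
#' @param features A `"corpus_features"` object.
#' @param dir Output directory (created if needed).
#' @return `dir` (write) or a `"corpus_features"` object (read).
#' @export
write_feature_cache <- function(features, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(features$is09, file.path(dir, "is09.csv"))
  con <- file(file.path(dir, "mel.bin"), "wb")
  for (m in features$mel) writeBin(as.numeric(m), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(ids = names(features$mel), size = features$size, params = features$params),
    file.path(dir, "mel.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_feature_cache
#' @export
read_feature_cache <- function(dir) {
  is09 <- readr::read_csv(file.path(dir, "is09.csv"), show_col_types = FALSE)
  side <- jsonlite::read_json(file.path(dir, "mel.json"), simplifyVector = TRUE)
  size <- as.integer(side$size)
  n_el <- size * size * 3L
  con <- file(file.path(dir, "mel.bin"), "rb")
  mel <- lapply(seq_along(side$ids), function(i) {
    array(readBin(con, "double", n_el, size = 8, endian = "little"), c(size, size, 3L))
  })
  close(con)
  names(mel) <- side$ids
  structure(list(is09 = is09, mel = mel, size = size, params = side$params),
            class = "corpus_features")
}
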