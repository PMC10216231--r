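#' Tidy the per-epoch training history
#'
#' @param x An `"aemt_fit"`.
#' @param ... Unused.
#' @return The history tibble: one row per epoch with losses, schedules and
#'   test metrics.
#' @export
tidy.aemt_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x An `"aemt_fit"`.
#' @param ... Unused.
#' @return Tibble with `epochs`, `best_epoch`, `best_accuracy`, `best_f1`,
#'   `final_accuracy`, `teacher_accuracy`, branch flags and scale.
#' @export
glance.aemt_fit <- function(x, ...) {
  h <- x$history
  b <- which.max(h$test_accuracy)
  tibble(epochs = nrow(h), best_epoch = h$epoch[b],
         best_accuracy = h$test_accuracy[b], best_f1 = h$test_f1[b],
         final_accuracy = h$test_accuracy[nrow(h)],
         teacher_accuracy = h$teacher_accuracy[nrow(h)],
         use_ae = x$cfg$use_ae, use_cnn = x$cfg$use_cnn,
         scale = x$cfg$scale)
}

#' Plot training curves
#'
#' Loss components and test accuracy per epoch.
#'
#' @param object An `"aemt_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aemt_fit <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(
    h[, c("epoch", "loss_ce", "loss_consis", "loss_recon",
          "test_accuracy", "teacher_accuracy")],
    -"epoch", names_to = "series", values_to = "value")
  long$panel <- ifelse(grepl("^loss", long$series), "loss", "test accuracy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ablation table
#'
#' @param object The tibble returned by [run_ablation()].
#' @param metric `"accuracy"` or `"f1"`.
#' @return A ggplot object.
#' @export
plot_ablation <- function(object, metric = "accuracy") {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$n_labeled),
                               y = .data[[metric]],
                               colour = .data$variant,
                               group = .data$variant)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::labs(x = "labeled examples", y = metric, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a mel-spectrum channel
#'
#' @param x A `H x H x 3` mel-spectrum array from [build_melspec3d()].
#' @param channel 1 (log-mel), 2 (delta) or 3 (delta-delta).
#' @return A ggplot object.
#' @export
plot_melspec <- function(x, channel = 1L) {
  d <- dim(x)
  df <- expand.grid(frame = seq_len(d[1L]), band = seq_len(d[2L]))
  df$value <- as.vector(x[, , channel])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$band,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (frames)", y = "mel band",
                  fill = c("log-mel", "delta", "delta-delta")[channel]) +
    ggplot2::theme_minimal()
}
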