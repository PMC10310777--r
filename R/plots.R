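# ggplot2 visualisation methods for the result objects.

#' Plot an axial slice of a volume or difference map
#'
#' @param x A [ct_volume()], 3D array, or `difference_map`.
#' @param slice Axial slice index (default: middle).
#' @param window Intensity window `c(lo, hi)`; defaults to the data range
#'   (or the clip range for a difference map).
#' @returns A ggplot.
#' @export
plot_slice <- function(x, slice = NULL, window = NULL) {
  if (inherits(x, "difference_map")) {
    v <- x$values
    if (is.null(window)) window <- x$range
    fill_lab <- "difference"
  } else {
    v <- vol_values(x)
    if (is.null(window)) window <- range(v)
    fill_lab <- "intensity"
  }
  if (is.null(slice)) slice <- dim(v)[3] %/% 2L
  sl <- v[, , slice]
  df <- tidyr::expand_grid(y = seq_len(ncol(sl)), x = seq_len(nrow(sl)))
  df$value <- as.numeric(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = pmin(pmax(.data$value, window[1]),
                                               window[2]))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey50",
                                  high = "white",
                                  midpoint = mean(window), name = fill_lab) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("axial slice ", slice)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.difference_map <- function(object, ...) plot_slice(object, ...)

#' Training-history curves
#'
#' @param object A `cyclegan_fit`.
#' @param ... Unused.
#' @returns A ggplot of every loss component against iteration.
#' @exportS3Method ggplot2::autoplot
autoplot.cyclegan_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"iteration",
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "loss",
                  title = "cycle-GAN training history") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @export
tidy.cyclegan_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"iteration",
                      names_to = "component", values_to = "value")
}

#' @export
glance.cyclegan_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  dplyr::bind_cols(
    tibble::tibble(iterations = nrow(x$history),
                   patch_size = x$cfg$patch_size,
                   base_filters = x$g_ab$spec$base_filters,
                   lambda_identity = x$weights$lambda_identity),
    last[, setdiff(names(last), "iteration")])
}

#' Learning-curve plot with error ribbons
#'
#' @param object A `curve_stats` from [train_head()].
#' @param metrics Metrics to show.
#' @param ... Unused.
#' @returns A ggplot: mean curve per split with a +/- SEM ribbon.
#' @exportS3Method ggplot2::autoplot
autoplot.curve_stats <- function(object,
                                 metrics = c("loss", "auc", "precision",
                                             "recall"), ...) {
  df <- dplyr::filter(object$curves, .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$mean,
                                   colour = .data$split,
                                   fill = .data$split)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "classification head learning curves") +
    ggplot2::theme_minimal()
}

#' Drift histograms per feature
#'
#' @param object A `drift_result` from [abs_pct_diff()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @returns A ggplot: one histogram of absolute percentage drift per
#'   feature.
#' @exportS3Method ggplot2::autoplot
autoplot.drift_result <- function(object, bins = 20L, ...) {
  ggplot2::ggplot(object$drift, ggplot2::aes(.data$drift_pct)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~feature, scales = "free_x") +
    ggplot2::labs(x = "absolute percentage difference (%)", y = "subjects",
                  title = "radiomic feature drift under style transfer") +
    ggplot2::theme_minimal()
}
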