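# ggplot2 graphics for each result type.

#' Plot a fitted or extrapolated density surface
#'
#' @param surface Tibble with `x`, `y` and a `density` column (e.g. from
#'   [predict_density()]).
#' @param fill Column to map to fill (default `density`).
#' @return A ggplot.
#' @export
plot_density_surface <- function(surface, fill = "density") {
  ggplot2::ggplot(surface, ggplot2::aes(x = x, y = y, fill = .data[[fill]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "bears / 1,000 km²") +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}

#' Plot detectors and detections on the landscape
#'
#' @param detectors Detector tibble.
#' @param history Optional detection tibble; detectors with detections are
#'   emphasized.
#' @return A ggplot.
#' @export
plot_detectors <- function(detectors, history = NULL) {
  p <- ggplot2::ggplot(detectors, ggplot2::aes(x = x, y = y, shape = type)) +
    ggplot2::geom_point(colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
  if (!is.null(history)) {
    hit <- detectors[detectors$detector %in% unique(history$detector), ]
    p <- p + ggplot2::geom_point(data = hit, colour = "firebrick", size = 2)
  }
  p
}

#' @rdname autoplot-ursadens
#' @export
autoplot.secr_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = estimate, y = term, colour = .data$parameter)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "coefficient (log-link scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' Coefficient plot for `secr_fit`, bin profile for `rsf_bins`, per-fold
#' Spearman coefficients for `rsf_cv`.
#'
#' @param object The fitted object.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-ursadens
#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

#' @rdname autoplot-ursadens
#' @export
autoplot.rsf_bins <- function(object, ...) {
  b <- object$bins
  ggplot2::ggplot(b, ggplot2::aes(x = factor(bin), y = area)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "RSF bin (scaled score)", y = "area (km²)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-ursadens
#' @export
autoplot.rsf_cv <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(x = factor(rep), y = .data$rs)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(yintercept = object$rs_bar, colour = "firebrick") +
    ggplot2::labs(x = "repeat", y = "Spearman rank correlation") +
    ggplot2::theme_minimal()
}

#' Compare SECR and RSF density estimates by region
#'
#' @param report Comparison tibble from [run_pipeline()] (columns `method`,
#'   `sex`, `region`, `density`, `lo_density`, `hi_density`).
#' @return A ggplot.
#' @export
plot_method_comparison <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = region, y = density, colour = method)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$lo_density, ymax = .data$hi_density),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = NULL, y = "bears / 1,000 km²") +
    ggplot2::theme_minimal()
}
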