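#' Plot a smoothed calibration curve
#'
#' Draws the smoothed observed-versus-predicted risk curve over the display
#' range, the diagonal of perfect calibration, and (optionally) a kernel
#' density of the predicted risks along the bottom to show where the
#' subjects actually lie.
#'
#' @param object A `cr_calibration` object from [calibration_curve()].
#' @param show_density Overlay a scaled density of the predicted risks.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cr_calibration
#' @export
autoplot.cr_calibration <- function(object, show_density = TRUE, ...) {
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c5f8a") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted risk", y = "Smoothed observed risk",
                  title = sprintf("Calibration at t0 = %.3g", object$t0),
                  subtitle = sprintf("ICI %.3f | E50 %.3f | E90 %.3f",
                                     object$metrics$ici, object$metrics$e50,
                                     object$metrics$e90)) +
    ggplot2::theme_minimal()
  if (show_density) {
    dens <- stats::density(object$predicted, from = 0, to = 1)
    dd <- tibble(x = dens$x, y = dens$y / max(dens$y) * 0.12)
    p <- p + ggplot2::geom_area(data = dd,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                fill = "grey70", alpha = 0.5,
                                inherit.aes = FALSE)
  }
  p
}

#' @export
plot.cr_calibration <- function(x, ...) print(autoplot(x, ...))

#' Plot aggregated study calibration curves
#'
#' Mean calibration curve per evaluation horizon with 2.5th/97.5th
#' percentile bands across replicates, faceted by horizon, one colour per
#' knot count.
#'
#' @param object A `cr_study` object from [run_study()].
#' @param scenario Index of the scenario to plot (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cr_study
#' @export
autoplot.cr_study <- function(object, scenario = 1L, ...) {
  res <- object[[scenario]]
  curves <- dplyr::mutate(res$curves, n_knots = factor(.data$n_knots))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$predicted, y = .data$mean,
                                       colour = .data$n_knots,
                                       fill = .data$n_knots)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::facet_wrap(~time_label, nrow = 1) +
    ggplot2::labs(x = "Predicted risk", y = "Smoothed observed risk",
                  colour = "knots", fill = "knots") +
    ggplot2::theme_minimal()
}

#' Plot a binned calibration comparator table
#'
#' @param binned Output of [binned_calibration()].
#' @return A ggplot object.
#' @export
plot_binned_calibration <- function(binned) {
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$mean_predicted,
                                       y = .data$observed)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 2, colour = "#2c5f8a") +
    ggplot2::labs(x = "Mean predicted risk (bin)",
                  y = "Observed risk (Aalen-Johansen CIF)") +
    ggplot2::theme_minimal()
}
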