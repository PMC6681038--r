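#' Plot methods
#'
#' ggplot2 visualisations for the main result types: `autoplot()` on a
#' `calibration_curve` draws the fitted line (with the calibration
#' points when the curve was fitted from data), on a `range_analysis`
#' the main-effects plot of level means per factor, and on a
#' `synthetic_sample` the simulated chromatogram trace.
#' `plot_spectrum()` draws a stick spectrum for an observed or
#' theoretical spectrum.
#'
#' @param object Object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name pmpms-plots
NULL

#' @rdname pmpms-plots
#' @export
autoplot.calibration_curve <- function(object, ...) {
  rng <- if (all(is.finite(object$linear_range))) object$linear_range else c(0, 1)
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::xlim(rng[1], rng[2]) +
    ggplot2::labs(x = "concentration (umol/L)", y = "peak area",
                  title = if (is.na(object$analyte)) "calibration" else object$analyte)
  if (!is.null(object$fit)) {
    d <- tibble(concentration = object$fit$model$x, area = object$fit$model$y)
    p <- p + ggplot2::geom_point(data = d,
                                 ggplot2::aes(x = .data$concentration, y = .data$area))
  }
  p
}

#' @rdname pmpms-plots
#' @export
autoplot.range_analysis <- function(object, ...) {
  ggplot2::ggplot(object$levels,
                  ggplot2::aes(x = factor(.data$level), y = .data$k, group = 1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~factor, nrow = 1) +
    ggplot2::labs(x = "level", y = "mean response")
}

#' @rdname pmpms-plots
#' @export
autoplot.synthetic_sample <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "retention time (min)", y = "intensity")
}

#' @rdname pmpms-plots
#' @param spectrum An [observed_spectrum()] or a [theoretical_spectrum()]
#'   tibble.
#' @export
plot_spectrum <- function(spectrum, ...) {
  if (inherits(spectrum, "observed_spectrum")) {
    d <- spectrum$peaks
    ttl <- sprintf("precursor m/z %.4f", spectrum$precursor_mz)
  } else {
    d <- tibble(mz = spectrum$mz,
                intensity = ifelse(spectrum$abundance == "high", 1, 0.2))
    ttl <- spectrum$target[1]
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                  y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment() +
    ggplot2::labs(x = "m/z", y = "relative intensity", title = ttl)
}
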