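#' Construct a calibration curve from known coefficients
#'
#' Represents a straight-line calibration `area = slope * concentration
#' + intercept` with its coefficient of determination and validated
#' linear range, e.g. curves taken from a published validation table.
#'
#' @param slope Peak area per umol/L (> 0).
#' @param intercept Peak area at zero concentration.
#' @param r_squared Coefficient of determination in \[0, 1\]
#'   (`NA` allowed when unknown).
#' @param linear_range Length-2 numeric, low < high, in umol/L.
#' @param analyte Optional analyte name.
#' @return A `calibration_curve` object.
#' @export
#' @examples
#' calibration_curve(2.3516e4, 1.5884e5, 0.9999, c(199.82, 3596.80), "glucose")
calibration_curve <- function(slope, intercept, r_squared = NA_real_,
                              linear_range = c(0, Inf), analyte = NA_character_) {
  check_positive(slope, "slope")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    abort("`r_squared` must lie in [0, 1]")
  }
  if (length(linear_range) != 2 || linear_range[1] >= linear_range[2]) {
    abort("`linear_range` must be c(low, high) with low < high")
  }
  structure(list(analyte = analyte, slope = slope, intercept = intercept,
                 r_squared = r_squared,
                 linear_range = as.numeric(linear_range), fit = NULL),
            class = "calibration_curve")
}

#' Fit a calibration curve by ordinary least squares
#'
#' Fits the unweighted regression of peak area on standard
#' concentration (area = slope x concentration + intercept). The
#' reported r-squared is the squared Pearson correlation between areas
#' and fitted values, and the linear range is taken as the span of the
#' calibration levels.
#'
#' @param data Data frame of calibration points.
#' @param concentration,area Column names (tidy-eval) holding standard
#'   concentrations (umol/L) and peak areas.
#' @param analyte Optional analyte name.
#' @return A `calibration_curve` with the underlying `lm` fit attached;
#'   use [tidy()] / [glance()] to extract coefficients and summaries.
#' @export
#' @examples
#' pts <- data.frame(conc = c(1, 2, 4, 8), area = c(3, 5, 9, 17))
#' glance(fit_calibration(pts, conc, area))
fit_calibration <- function(data, concentration, area, analyte = NA_character_) {
  x <- dplyr::pull(data, {{ concentration }})
  y <- dplyr::pull(data, {{ area }})
  if (length(x) < 3) abort("calibration needs at least 3 points")
  if (length(unique(x)) < 2 || sd(x) == 0) {
    abort("calibration concentrations must vary")
  }
  fit <- lm(y ~ x)
  r2 <- if (sd(y) == 0) 1 else stats::cor(y, stats::fitted(fit))^2
  out <- calibration_curve(slope = unname(coef(fit)[2]),
                           intercept = unname(coef(fit)[1]),
                           r_squared = r2,
                           linear_range = range(x),
                           analyte = analyte)
  out$fit <- fit
  out
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve>%s y = %.6g x + %.6g, R2 = %s, range [%g, %g] umol/L\n",
              if (is.na(x$analyte)) "" else paste0(" ", x$analyte, ":"),
              x$slope, x$intercept,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              x$linear_range[1], x$linear_range[2]))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_calibration
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(analyte = x$analyte, slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared,
         range_low = x$linear_range[1], range_high = x$linear_range[2])
}

#' Detection and quantification limits from baseline noise
#'
#' The limits of detection and quantification are the concentrations
#' whose signal reaches 3 and 10 times the baseline noise standard
#' deviation: `LOD = 3 * noise_sd / slope`, `LOQ = 10 * noise_sd /
#' slope`, so LOQ is always 10/3 of LOD.
#'
#' @param noise_sd Baseline noise standard deviation, in area units.
#' @param curve A [calibration_curve()].
#' @return A tibble with `analyte`, `lod` and `loq` (umol/L).
#' @export
#' @examples
#' cv <- calibration_curve(3e4, 0, linear_range = c(1, 100))
#' lod_loq(3e4 / 3, cv)  # lod = 1 umol/L
lod_loq <- function(noise_sd, curve) {
  check_positive(noise_sd, "noise_sd")
  tibble(analyte = curve$analyte,
         lod = 3 * noise_sd / curve$slope,
         loq = 10 * noise_sd / curve$slope)
}

#' Back-calculate concentration from a peak area
#'
#' Inverts the calibration line: `(area - intercept) / slope`. The
#' `in_range` flag marks whether the result lies inside the curve's
#' validated linear range.
#'
#' @param area Numeric vector of peak areas.
#' @param curve A [calibration_curve()].
#' @return A tibble with `area`, `concentration` (umol/L) and
#'   `in_range`.
#' @export
#' @examples
#' cv <- calibration_curve(2, 1, linear_range = c(0.5, 200))
#' back_calculate(c(1, 201), cv)
back_calculate <- function(area, curve) {
  conc <- (area - curve$intercept) / curve$slope
  # endpoints count as in range; tolerate round-trip floating-point noise
  eps <- 1e-9 * pmax(1, abs(curve$linear_range))
  tibble(area = area, concentration = conc,
         in_range = conc >= curve$linear_range[1] - eps[1] &
           conc <= curve$linear_range[2] + eps[2])
}
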