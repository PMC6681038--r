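#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported m/z, ppm and percentage
#' values in this package follow the conventional half-up rule instead
#' (e.g. `round_half_up(0.625, 2)` is 0.63, not 0.62).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.125, -0.125), 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# internal: stop unless all values are finite, positive numbers
check_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0("`", what, "` must be positive and finite"))
  }
  invisible(x)
}
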