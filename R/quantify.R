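#' Conversion constants from solution concentration to sample content
#'
#' The hydrolysis/derivatization workflow that links the injected
#' solution back to the weighed polysaccharide: `sample_mass_mg` of
#' polysaccharide is hydrolyzed and the dried hydrolysate dissolved in
#' `dissolution_volume_ml`; an aliquot of `aliquot_volume_ml` is
#' derivatized and made up to `final_volume_ml` for injection. A
#' concentration c (umol/L = nmol/mL) in the injected solution then
#' corresponds to a content of
#' `c * final_volume * dissolution_volume / aliquot_volume /
#' sample_mass` nmol per mg. With the defaults (20 mg, 5 mL, 0.1 mL,
#' 1 mL) the factor is 2.5.
#'
#' @param sample_mass_mg Polysaccharide mass hydrolyzed (mg).
#' @param dissolution_volume_ml Volume the hydrolysate is dissolved in
#'   (mL).
#' @param aliquot_volume_ml Aliquot taken for derivatization (mL).
#' @param final_volume_ml Final volume of the injected solution (mL).
#' @return A `content_constants` list with the four constants and the
#'   derived `factor` ((nmol/mg) per (umol/L)).
#' @export
#' @examples
#' content_constants()$factor  # 2.5
content_constants <- function(sample_mass_mg = 20, dissolution_volume_ml = 5,
                              aliquot_volume_ml = 0.1, final_volume_ml = 1) {
  for (v in c(sample_mass_mg, dissolution_volume_ml, aliquot_volume_ml,
              final_volume_ml)) check_positive(v, "content constants")
  structure(list(sample_mass_mg = sample_mass_mg,
                 dissolution_volume_ml = dissolution_volume_ml,
                 aliquot_volume_ml = aliquot_volume_ml,
                 final_volume_ml = final_volume_ml,
                 factor = final_volume_ml * dissolution_volume_ml /
                   aliquot_volume_ml / sample_mass_mg),
            class = "content_constants")
}

#' Convert solution concentration to polysaccharide content
#'
#' `to_content()` maps umol/L in the injected solution to nmol per mg
#' of polysaccharide via the [content_constants()] factor;
#' `from_content()` is its exact inverse.
#'
#' @param concentration Concentration(s) in umol/L.
#' @param content Content(s) in nmol/mg.
#' @param constants A [content_constants()] object.
#' @return Numeric vector (nmol/mg for `to_content`, umol/L for
#'   `from_content`).
#' @export
#' @examples
#' to_content(100)            # 250 nmol/mg with the default workflow
#' from_content(to_content(7))
to_content <- function(concentration, constants = content_constants()) {
  if (any(concentration < 0)) abort("`concentration` must be >= 0")
  concentration * constants$factor
}

#' @rdname to_content
#' @export
from_content <- function(content, constants = content_constants()) {
  if (any(content < 0)) abort("`content` must be >= 0")
  content / constants$factor
}

#' Spike recovery percentage
#'
#' `recovery (%) = (found - original) / spiked * 100`, the standard
#' accuracy check where a known amount is spiked into a sample of known
#' content and re-analyzed. Invariant under a common rescaling of the
#' three amounts; reported half-up at 2 decimal places.
#'
#' @param found Total amount detected after spiking (any common unit).
#' @param original Amount originally present.
#' @param spiked Amount spiked (> 0).
#' @param digits Decimal places for the reported percentage (default 2;
#'   use `NULL` for full precision).
#' @return Recovery percentage(s).
#' @export
#' @examples
#' recovery(470.88, 234.88, 230)  # 102.61
recovery <- function(found, original, spiked, digits = 2) {
  check_positive(spiked, "spiked")
  out <- (found - original) / spiked * 100
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Relative standard deviation
#'
#' `RSD (%) = sd / mean * 100` with the sample (n - 1) standard
#' deviation, the precision/repeatability/stability statistic for small
#' replicate series.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @param digits Decimal places (default 2; `NULL` for full precision).
#' @return RSD as a percentage.
#' @export
#' @examples
#' rsd(c(1, 2, 3))  # 50
rsd <- function(values, digits = 2) {
  if (length(values) < 2) abort("RSD needs at least 2 values")
  m <- mean(values)
  if (m == 0) abort("RSD undefined for zero-mean values")
  out <- sd(values) / m * 100
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Summarize a per-sample monosaccharide content table
#'
#' Takes a long content table (one row per sample x analyte) and
#' reports the global extremes, per-analyte ranges across samples, and
#' the within-sample abundance ranking of analytes (rank 1 = most
#' abundant).
#'
#' @param data Data frame with one content value per sample/analyte
#'   pair.
#' @param sample,analyte,content Column names (tidy-eval).
#' @return A list of class `sample_summary`: `overall` (one-row tibble
#'   with `min_content`, `min_sample`, `min_analyte`, `max_content`,
#'   `max_sample`, `max_analyte`, `n_samples`, `n_analytes`),
#'   `per_analyte` (min/max/mean per analyte) and `rankings` (long
#'   tibble with within-sample `rank`).
#' @export
#' @examples
#' tbl <- data.frame(sample = rep(c("a", "b"), each = 2),
#'                   analyte = rep(c("glc", "man"), 2),
#'                   content = c(30, 3, 28, 5))
#' summarize_samples(tbl, sample, analyte, content)$overall
summarize_samples <- function(data, sample, analyte, content) {
  long <- dplyr::transmute(data, sample = {{ sample }},
                           analyte = {{ analyte }}, content = {{ content }})
  if (nrow(long) == 0) abort("content table is empty")
  i_min <- which.min(long$content)
  i_max <- which.max(long$content)
  overall <- tibble(
    min_content = long$content[i_min], min_sample = long$sample[i_min],
    min_analyte = long$analyte[i_min],
    max_content = long$content[i_max], max_sample = long$sample[i_max],
    max_analyte = long$analyte[i_max],
    n_samples = dplyr::n_distinct(long$sample),
    n_analytes = dplyr::n_distinct(long$analyte)
  )
  per_analyte <- long |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(min = min(.data$content), max = max(.data$content),
                     mean = mean(.data$content), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean))
  rankings <- long |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(rank = rank(-.data$content, ties.method = "min")) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample, .data$rank)
  structure(list(overall = overall, per_analyte = per_analyte,
                 rankings = rankings),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<sample_summary> %d samples x %d analytes\n",
              o$n_samples, o$n_analytes))
  cat(sprintf("  min %.2f (%s, %s); max %.2f (%s, %s)\n",
              o$min_content, o$min_sample, o$min_analyte,
              o$max_content, o$max_sample, o$max_analyte))
  invisible(x)
}
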