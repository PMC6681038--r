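#' The six monosaccharide mass classes
#'
#' Common reducing monosaccharides fall into six groups by molecular
#' weight: hexose (C6H12O6), hexosamine (C6H13NO5), pentose (C5H10O5),
#' tetrose (C4H8O4), methylpentose/deoxyhexose (C6H12O5) and hexuronic
#' acid (C6H10O7). Members of a class are isobaric and share one
#' quasimolecular ion; they are told apart chromatographically.
#'
#' @return A tibble with one row per class: `class_name`, `carbon_count`,
#'   the atom counts `c`, `h`, `n`, `o`, `base_composition` (list column
#'   of [comp()] objects) and `base_mass` (monoisotopic, Da).
#' @export
#' @examples
#' sugar_classes()
sugar_classes <- function() {
  out <- tibble(
    class_name = c("hexose", "hexosamine", "pentose", "tetrose",
                   "methylpentose", "hexuronic_acid"),
    carbon_count = c(6L, 6L, 5L, 4L, 6L, 6L),
    c = c(6L, 6L, 5L, 4L, 6L, 6L),
    h = c(12L, 13L, 10L, 8L, 12L, 10L),
    n = c(0L, 1L, 0L, 0L, 0L, 0L),
    o = c(6L, 5L, 5L, 4L, 5L, 7L)
  )
  out$base_composition <- purrr::pmap(out[, c("c", "h", "n", "o")], comp)
  out$base_mass <- purrr::map_dbl(out$base_composition, monoisotopic_mass)
  out
}

#' Reference library of the 12 monosaccharides
#'
#' The 12 PMP-labeled monosaccharides released by polysaccharide
#' hydrolysis, with their mass class and reference retention time
#' (minutes) on the reference separation (0.1 mol/L ammonium
#' acetate/acetonitrile, C18, 180 min). Retention times are strictly
#' increasing in elution order: mannose, glucosamine, lyxose, rhamnose,
#' ribose, erythrose, glucuronic acid, galacturonic acid, glucose,
#' galactose, xylose, fucose. Isobaric species (e.g. the three hexoses)
#' are distinguished only by retention time.
#'
#' @return A tibble with columns `species`, `class_name`,
#'   `reference_rt` (min) and `elution_order`.
#' @export
#' @examples
#' species_library()
species_library <- function() {
  tibble(
    species = c("mannose", "glucosamine", "lyxose", "rhamnose", "ribose",
                "erythrose", "glucuronic acid", "galacturonic acid",
                "glucose", "galactose", "xylose", "fucose"),
    class_name = c("hexose", "hexosamine", "pentose", "methylpentose",
                   "pentose", "tetrose", "hexuronic_acid", "hexuronic_acid",
                   "hexose", "hexose", "pentose", "methylpentose"),
    reference_rt = c(33.830, 36.548, 40.298, 47.701, 48.832, 64.678,
                     94.865, 107.503, 115.318, 130.080, 145.282, 166.837),
    elution_order = 1:12
  )
}
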