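# CSV dialect shared by all table readers: comma-separated, header row,
# UTF-8, "." decimal separator. Typographic dashes/minus signs (common
# when tables are copied from typeset documents) are normalized to
# ASCII, and a bare "-" cell means "not detected" and becomes NA.

normalize_dashes <- function(x) {
  x <- gsub("−|–|—", "-", x)
  x[trimws(x) == "-"] <- NA_character_
  trimws(x)
}

read_clean_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(df) == 0) abort(paste0("no data rows in ", path))
  dplyr::mutate(df, dplyr::across(dplyr::everything(), normalize_dashes))
}

to_num <- function(df, cols, path) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(!is.na(df[[cl]]) & is.na(v))
    if (length(bad) > 0) {
      abort(paste0("malformed numeric value in ", path, ", column `", cl,
                   "`, data row ", bad[1]))
    }
    df[[cl]] <- v
  }
  df
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "pmpms", mustWork = TRUE)
}

#' Reference MS1/MS2 ion table of the 12 PMP-labeled monosaccharides
#'
#' Reads the packaged reference table (or a user file in the same
#' dialect): one row per species with its retention time, measured
#' quasimolecular ion, printed ppm error and the twelve characteristic
#' MS2 fragment columns. "Not detected" cells are `NA`.
#'
#' @param path CSV path; defaults to the packaged reference table.
#' @return A 12-row tibble.
#' @export
#' @examples
#' read_reference_ions()
read_reference_ions <- function(path = fixture_path("reference_ions.csv")) {
  df <- read_clean_csv(path)
  num_cols <- setdiff(names(df), "species")
  df <- to_num(df, num_cols, path)
  if (!all(c("rt_min", "species", "precursor_mz") %in% names(df))) {
    abort("reference ion table needs rt_min, species, precursor_mz columns")
  }
  df
}

#' @rdname read_reference_ions
#' @return For `reference_ion_columns()`: a tibble mapping each
#'   fragment column of the reference table to the [fragment_rules()]
#'   rule ids that may populate it (the base rule and, where one
#'   exists, its hexosamine variant).
#' @export
reference_ion_columns <- function() {
  tibble(
    column = c("precursor_minus_water", "c3c4_cleavage_water",
               "c2c3_cleavage_water", "loss_pmp", "loss_pmp_water",
               "loss_pmp_2water", "loss_pmp_3water", "c5c6_cleavage",
               "c4c5_cleavage", "c2c3_cleavage", "c1c2_cleavage",
               "pmp_reporter"),
    rule_ids = list(
      "precursor_minus_water",
      c("c3c4_cleavage_water", "c3c4_cleavage_water_amino"),
      c("c2c3_cleavage_water", "c2c3_cleavage_water_amino"),
      "loss_pmp",
      c("loss_pmp_water", "loss_pmp_ammonia"),
      c("loss_pmp_2water", "loss_pmp_ammonia_water"),
      c("loss_pmp_3water", "loss_pmp_ammonia_2water"),
      c("c5c6_cleavage", "c5c6_cleavage_amino"),
      c("c4c5_cleavage", "c4c5_cleavage_amino"),
      c("c2c3_cleavage", "c2c3_cleavage_amino"),
      "c1c2_cleavage",
      "pmp_reporter")
  )
}

#' Published validation tables
#'
#' Readers for the packaged validation fixtures (or user files in the
#' same dialect): `read_calibration_table()` - calibration lines,
#' r-squared, linear ranges and LOD/LOQ per analyte;
#' `read_recovery_table()` - original/spiked/found amounts with
#' recovery and RSD; `read_content_table()` - per-sample monosaccharide
#' contents (nmol/mg), wide format with one column per analyte.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return A tibble (10, 10 and 12 rows respectively for the packaged
#'   fixtures).
#' @export
#' @examples
#' read_calibration_table()
read_calibration_table <- function(path = fixture_path("calibration_reference.csv")) {
  df <- read_clean_csv(path)
  need <- c("analyte", "slope", "intercept", "r_squared",
            "range_low", "range_high", "lod", "loq")
  if (!all(need %in% names(df))) {
    abort(paste0("calibration table needs columns: ", paste(need, collapse = ", ")))
  }
  to_num(df, setdiff(need, "analyte"), path)
}

#' @rdname read_calibration_table
#' @export
read_recovery_table <- function(path = fixture_path("recovery_reference.csv")) {
  df <- read_clean_csv(path)
  need <- c("analyte", "original", "spiked", "found", "recovery_pct", "rsd_pct")
  if (!all(need %in% names(df))) {
    abort(paste0("recovery table needs columns: ", paste(need, collapse = ", ")))
  }
  to_num(df, setdiff(need, "analyte"), path)
}

#' @rdname read_calibration_table
#' @export
read_content_table <- function(path = fixture_path("sample_contents.csv")) {
  df <- read_clean_csv(path)
  if (!"sample" %in% names(df)) abort("content table needs a `sample` column")
  to_num(df, setdiff(names(df), c("sample", "origin")), path)
}

#' Pivot a wide content table to long form
#'
#' Helper turning the one-column-per-analyte layout of
#' [read_content_table()] into the long (sample, analyte, content)
#' layout that [summarize_samples()] consumes.
#'
#' @param data Wide content table.
#' @return A long tibble with `sample`, `analyte`, `content`.
#' @export
#' @examples
#' contents_long(read_content_table()) |> head()
contents_long <- function(data) {
  tidyr::pivot_longer(data, cols = -dplyr::any_of(c("sample", "origin")),
                      names_to = "analyte", values_to = "content")
}

#' Turn the published calibration table into curve objects
#'
#' @param data A calibration table as returned by
#'   [read_calibration_table()].
#' @return A named list of [calibration_curve()] objects keyed by
#'   analyte.
#' @export
#' @examples
#' calibration_curves()[["glucose"]]
calibration_curves <- function(data = read_calibration_table()) {
  curves <- purrr::pmap(
    data[, c("analyte", "slope", "intercept", "r_squared", "range_low", "range_high")],
    function(analyte, slope, intercept, r_squared, range_low, range_high) {
      calibration_curve(slope, intercept, r_squared, c(range_low, range_high),
                        analyte)
    })
  setNames(curves, data$analyte)
}

#' Read and write LC-MS peak tables
#'
#' A peak table holds one row per chromatographic peak with at least
#' `rt` (minutes) and `area`; `precursor_mz` and `species` columns are
#' kept when present. The writer emits the same CSV dialect the reader
#' consumes, so round trips preserve values.
#'
#' @param path CSV path.
#' @param peaks A data frame with at least `rt` and `area`.
#' @return `read_peak_table()`: a tibble; `write_peak_table()`:
#'   `path`, invisibly.
#' @export
read_peak_table <- function(path) {
  df <- read_clean_csv(path)
  if (!all(c("rt", "area") %in% names(df))) {
    abort("peak table needs `rt` and `area` columns")
  }
  to_num(df, intersect(names(df), c("rt", "area", "precursor_mz", "height")), path)
}

#' @rdname read_peak_table
#' @export
write_peak_table <- function(peaks, path) {
  if (!all(c("rt", "area") %in% names(peaks))) {
    abort("peak table needs `rt` and `area` columns")
  }
  readr::write_csv(peaks, path)
  invisible(path)
}

#' Export theoretical spectra as delimited text
#'
#' Writes the [theoretical_spectrum()] of each target to one CSV
#' (columns target, class_name, rule_id, abundance, mz).
#'
#' @param targets Character vector of class or species names.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_theoretical_spectra <- function(targets, path) {
  tbl <- purrr::map_dfr(targets, theoretical_spectrum)
  readr::write_csv(tbl[, c("target", "class_name", "rule_id", "abundance", "mz")],
                   path)
  invisible(path)
}
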