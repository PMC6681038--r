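#' Observed (centroided) MS2 spectrum
#'
#' Container for one product-ion spectrum: precursor m/z, retention
#' time and a peak list. Intensities are normalized so the base peak is
#' 1 and peaks are kept sorted by m/z.
#'
#' @param precursor_mz Precursor m/z of the selected ion.
#' @param rt Retention time in minutes.
#' @param peaks A data frame with numeric columns `mz` and `intensity`
#'   (an empty peak list is allowed).
#' @return An `observed_spectrum` object (list with `precursor_mz`,
#'   `rt` and the normalized `peaks` tibble).
#' @export
#' @examples
#' observed_spectrum(511.2187, 115.3,
#'                   data.frame(mz = c(175.09, 187.09), intensity = c(10, 4)))
observed_spectrum <- function(precursor_mz, rt, peaks) {
  check_positive(precursor_mz, "precursor_mz")
  if (!is.numeric(rt) || length(rt) != 1 || !is.finite(rt)) {
    abort("`rt` must be a single finite number (minutes)")
  }
  peaks <- as_tibble(peaks)
  if (nrow(peaks) > 0) {
    if (!all(c("mz", "intensity") %in% names(peaks))) {
      abort("`peaks` needs `mz` and `intensity` columns")
    }
    peaks <- peaks[, c("mz", "intensity")]
    check_positive(peaks$mz, "peaks$mz")
    if (any(peaks$intensity < 0)) abort("peak intensities must be >= 0")
    if (max(peaks$intensity) > 0) {
      peaks$intensity <- peaks$intensity / max(peaks$intensity)
    }
    peaks <- dplyr::arrange(peaks, .data$mz)
  } else {
    peaks <- tibble(mz = numeric(), intensity = numeric())
  }
  structure(list(precursor_mz = precursor_mz, rt = rt, peaks = peaks),
            class = "observed_spectrum")
}

#' @export
print.observed_spectrum <- function(x, ...) {
  cat(sprintf("<observed_spectrum> precursor m/z %.4f, rt %.3f min, %d peaks\n",
              x$precursor_mz, x$rt, nrow(x$peaks)))
  invisible(x)
}

#' Read MS2 spectra from an MGF file
#'
#' Parses the Mascot generic format dialect used throughout the
#' package: `BEGIN IONS` / `END IONS` blocks with `PEPMASS=`,
#' `RTINSECONDS=` (converted to minutes) and whitespace-separated
#' `m/z intensity` pairs. Unknown `KEY=value` headers are ignored.
#'
#' @param path Path to an MGF text file.
#' @return A list of [observed_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    abort(paste0("malformed MGF file: unbalanced BEGIN/END IONS in ", path))
  }
  purrr::map2(starts, ends, function(s, e) {
    block <- lines[(s + 1):(e - 1)]
    headers <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[headers], "=", fixed = TRUE)
    keys <- toupper(purrr::map_chr(kv, 1))
    vals <- purrr::map_chr(kv, 2)
    if (!"PEPMASS" %in% keys) abort("MGF block lacks PEPMASS")
    pep <- as.numeric(strsplit(trimws(vals[keys == "PEPMASS"][1]), "\\s+")[[1]][1])
    rt_s <- if ("RTINSECONDS" %in% keys) as.numeric(vals[keys == "RTINSECONDS"][1]) else NA_real_
    peak_lines <- block[!headers & nzchar(block)]
    if (length(peak_lines) > 0) {
      mat <- do.call(rbind, lapply(strsplit(peak_lines, "[[:space:],]+"), function(p) {
        v <- suppressWarnings(as.numeric(p[1:2]))
        if (anyNA(v)) abort(paste0("malformed peak line in ", path, ": ", p[1]))
        v
      }))
      peaks <- tibble(mz = mat[, 1], intensity = mat[, 2])
    } else {
      peaks <- tibble(mz = numeric(), intensity = numeric())
    }
    observed_spectrum(pep, if (is.na(rt_s)) NA_real_ else rt_s / 60, peaks)
  })
}

#' Write MS2 spectra to an MGF file
#'
#' Inverse of [read_mgf()]: each spectrum becomes a `BEGIN IONS` block
#' with `PEPMASS`, `RTINSECONDS` and full-precision peak pairs, so a
#' read/write round trip preserves values.
#'
#' @param spectra A list of [observed_spectrum()] objects (or a single
#'   one).
#' @param path Output file path.
#' @param titles Optional character vector of TITLE lines.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path, titles = NULL) {
  if (inherits(spectra, "observed_spectrum")) spectra <- list(spectra)
  blocks <- purrr::imap(spectra, function(sp, i) {
    c("BEGIN IONS",
      if (!is.null(titles)) paste0("TITLE=", titles[[i]]),
      sprintf("PEPMASS=%.6f", sp$precursor_mz),
      if (!is.na(sp$rt)) sprintf("RTINSECONDS=%.4f", sp$rt * 60),
      sprintf("%.6f %.8g", sp$peaks$mz, sp$peaks$intensity),
      "END IONS", "")
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}
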