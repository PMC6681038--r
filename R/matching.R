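#' Match an observed MS2 spectrum against a theoretical spectrum
#'
#' Scores how well an observed product-ion spectrum agrees with the
#' rule-based theoretical spectrum of a sugar class or species. The
#' precursor must agree with the class quasimolecular ion within
#' `ms1_tol_ppm`; each theoretical fragment is matched if any observed
#' peak lies within `ms2_tol` Da. The score is the weighted fraction of
#' applicable rules matched (weight 2 for expected high abundance, 1
#' for low), so it lies in \[0, 1\], is 1 for a complete match and never
#' increases when a matched peak is removed. The hexosamine diagnostic
#' flag is set when both amino cleavage ions (nominal m/z 372 and 402)
#' are matched by peaks at relative intensity at or above
#' `diagnostic_threshold`.
#'
#' @param obs An [observed_spectrum()].
#' @param target Sugar class or species name (see
#'   [theoretical_spectrum()]).
#' @param ms2_tol Fragment tolerance in Da (default 0.05, matching
#'   ion-trap MS2 accuracy).
#' @param ms1_tol_ppm Precursor tolerance in ppm (default 10, TOF MS1
#'   accuracy).
#' @param diagnostic_threshold Minimum relative intensity for the
#'   hexosamine 372/402 diagnostics (default 0.2).
#' @param rules Rule set, defaulting to [fragment_rules()].
#' @return A one-row tibble: `target`, `class_name`, `score`,
#'   `precursor_ok`, `n_matched`, `n_theoretical`,
#'   `hexosamine_diagnostics` and a `fragments` list column with the
#'   per-fragment table (`rule_id`, `theoretical_mz`, `observed_mz`,
#'   `delta_mz`, `intensity`, `matched`).
#' @export
#' @examples
#' theo <- theoretical_spectrum("glucose")
#' obs <- observed_spectrum(511.2187, 115.3,
#'                          data.frame(mz = theo$mz, intensity = 1))
#' match_spectrum(obs, "glucose")$score
match_spectrum <- function(obs, target, ms2_tol = 0.05, ms1_tol_ppm = 10,
                           diagnostic_threshold = 0.2, rules = fragment_rules()) {
  check_positive(ms2_tol, "ms2_tol")
  check_positive(ms1_tol_ppm, "ms1_tol_ppm")
  theo <- theoretical_spectrum(target, rules = rules)
  class_name <- theo$class_name[1]
  precursor_ok <- abs(ppm_error(obs$precursor_mz, derivative_mz(class_name))) <= ms1_tol_ppm

  frag <- theo[, c("rule_id", "abundance", "mz")]
  names(frag)[names(frag) == "mz"] <- "theoretical_mz"
  if (nrow(obs$peaks) > 0 && precursor_ok) {
    nearest <- purrr::map_int(frag$theoretical_mz, function(m) {
      which.min(abs(obs$peaks$mz - m))
    })
    frag$observed_mz <- obs$peaks$mz[nearest]
    frag$intensity <- obs$peaks$intensity[nearest]
    frag$delta_mz <- frag$observed_mz - frag$theoretical_mz
    frag$matched <- abs(frag$delta_mz) <= ms2_tol
    frag$observed_mz[!frag$matched] <- NA_real_
    frag$intensity[!frag$matched] <- NA_real_
    frag$delta_mz[!frag$matched] <- NA_real_
  } else {
    frag$observed_mz <- NA_real_
    frag$intensity <- NA_real_
    frag$delta_mz <- NA_real_
    frag$matched <- FALSE
  }
  weight <- ifelse(frag$abundance == "high", 2, 1)
  score <- if (sum(weight) > 0) sum(weight[frag$matched]) / sum(weight) else 0

  diag_rules <- hexosamine_diagnostic_rules()
  diag <- class_name == "hexosamine" &&
    all(diag_rules %in% frag$rule_id) &&
    all(frag$matched[frag$rule_id %in% diag_rules]) &&
    all(frag$intensity[frag$rule_id %in% diag_rules] >= diagnostic_threshold)

  tibble(
    target = target, class_name = class_name,
    score = score, precursor_ok = precursor_ok,
    n_matched = sum(frag$matched), n_theoretical = nrow(frag),
    hexosamine_diagnostics = diag,
    fragments = list(frag)
  )
}

#' Identify a monosaccharide from one MS2 spectrum
#'
#' Candidate species are those whose class quasimolecular ion matches
#' the observed precursor within `ms1_tol_ppm` and whose reference
#' retention time lies within `rt_window` minutes of the observed one
#' (isobaric sugars such as mannose/glucose/galactose are separated
#' only chromatographically, so the window must stay below half the
#' closest same-class retention gap). Candidates are ranked by fragment
#' score, then by smaller retention-time deviation, then alphabetically
#' - a deterministic tie-break.
#'
#' @param obs An [observed_spectrum()] with a retention time.
#' @param library Species library, defaulting to [species_library()].
#' @param rt_window Retention-time window in minutes (default 1.0).
#' @inheritParams match_spectrum
#' @return A tibble of ranked candidates (possibly zero rows, not an
#'   error): `species`, `class_name`, `score`, `rt_dev`,
#'   `hexosamine_diagnostics`, `rank`.
#' @export
#' @examples
#' theo <- theoretical_spectrum("galactose")
#' obs <- observed_spectrum(511.2187, 130.1,
#'                          data.frame(mz = theo$mz, intensity = 1))
#' identify_spectrum(obs)
identify_spectrum <- function(obs, library = species_library(), rt_window = 1.0,
                              ms2_tol = 0.05, ms1_tol_ppm = 10,
                              rules = fragment_rules()) {
  check_positive(rt_window, "rt_window")
  if (nrow(library) == 0) abort("`library` must be non-empty")
  prec_ok <- abs(ppm_error(obs$precursor_mz,
                           derivative_mz(library$class_name))) <= ms1_tol_ppm
  rt_dev <- abs(obs$rt - library$reference_rt)
  cand <- library[prec_ok & !is.na(rt_dev) & rt_dev <= rt_window, ]
  if (nrow(cand) == 0) {
    return(tibble(species = character(), class_name = character(),
                  score = numeric(), rt_dev = numeric(),
                  hexosamine_diagnostics = logical(), rank = integer()))
  }
  scored <- purrr::map_dfr(cand$species, function(sp) {
    m <- match_spectrum(obs, sp, ms2_tol = ms2_tol, ms1_tol_ppm = ms1_tol_ppm,
                        rules = rules)
    tibble(species = sp, class_name = m$class_name, score = m$score,
           rt_dev = abs(obs$rt - cand$reference_rt[cand$species == sp]),
           hexosamine_diagnostics = m$hexosamine_diagnostics)
  })
  scored <- dplyr::arrange(scored, dplyr::desc(.data$score), .data$rt_dev,
                           .data$species)
  scored$rank <- seq_len(nrow(scored))
  scored
}

#' Identify a batch of MS2 spectra
#'
#' Runs [identify_spectrum()] over a list of spectra and returns the
#' top-ranked assignment per spectrum (spectra with no candidate yield
#' an `NA` assignment row rather than being dropped).
#'
#' @param spectra List of [observed_spectrum()] objects.
#' @inheritParams identify_spectrum
#' @return A tibble with one row per spectrum: `spectrum`,
#'   `precursor_mz`, `rt`, `species`, `class_name`, `score`,
#'   `rt_dev`, `hexosamine_diagnostics`.
#' @export
identify_spectra <- function(spectra, library = species_library(),
                             rt_window = 1.0, ms2_tol = 0.05, ms1_tol_ppm = 10,
                             rules = fragment_rules()) {
  purrr::imap_dfr(spectra, function(obs, i) {
    hits <- identify_spectrum(obs, library = library, rt_window = rt_window,
                              ms2_tol = ms2_tol, ms1_tol_ppm = ms1_tol_ppm,
                              rules = rules)
    top <- if (nrow(hits) > 0) hits[1, ] else
      tibble(species = NA_character_, class_name = NA_character_,
             score = NA_real_, rt_dev = NA_real_,
             hexosamine_diagnostics = NA)
    tibble(spectrum = i, precursor_mz = obs$precursor_mz, rt = obs$rt,
           species = top$species, class_name = top$class_name,
           score = top$score, rt_dev = top$rt_dev,
           hexosamine_diagnostics = top$hexosamine_diagnostics)
  })
}
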