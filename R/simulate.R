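#' Configuration for the synthetic LC-MS sample generator
#'
#' Bundles the ground-truth contents and every noise knob of
#' [simulate_sample()]. Defaults emulate the reference separation:
#' Gaussian chromatographic peaks of constant width (sd 0.2 min) on a
#' 0-180 min window, ~1% relative area noise (the order of the
#' validation RSDs), additive Gaussian baseline noise, bounded m/z
#' jitter (5 ppm on precursors, 0.02 Da on MS2 fragments, inside the
#' 10 ppm / 0.05 Da matching tolerances), retention-time jitter of sd
#' 0.1 min, and five uniform decoy peaks per MS2 spectrum over the
#' m/z 100-700 scan range.
#'
#' @param contents Named numeric vector of true contents (nmol/mg) per
#'   species; names must be [species_library()] species.
#' @param seed Integer random seed (mandatory: every simulation is
#'   reproducible).
#' @param peak_width_sd Chromatographic peak sd in minutes.
#' @param area_rel_noise Relative (multiplicative) sd of peak areas.
#' @param baseline_sd Additive baseline noise sd of the sampled trace,
#'   in intensity units.
#' @param ms1_jitter_ppm Half-width of the uniform precursor m/z
#'   jitter, ppm.
#' @param ms2_jitter_da Half-width of the uniform fragment m/z jitter,
#'   Da.
#' @param rt_jitter_sd Gaussian retention-time jitter sd, minutes.
#' @param n_decoy_peaks Number of random decoy peaks added to each MS2
#'   spectrum.
#' @param low_abundance_intensity Relative intensity given to
#'   low-abundance fragment rules (high-abundance rules get 1).
#' @param constants [content_constants()] linking content to solution
#'   concentration.
#' @return A `synthetic_sample_config` list.
#' @export
synthetic_sample_config <- function(contents, seed,
                                    peak_width_sd = 0.2,
                                    area_rel_noise = 0.01,
                                    baseline_sd = 50,
                                    ms1_jitter_ppm = 5,
                                    ms2_jitter_da = 0.02,
                                    rt_jitter_sd = 0.1,
                                    n_decoy_peaks = 5,
                                    low_abundance_intensity = 0.1,
                                    constants = content_constants()) {
  if (is.null(names(contents)) || any(!nzchar(names(contents)))) {
    abort("`contents` must be a named vector (species -> nmol/mg)")
  }
  if (any(contents < 0)) abort("contents must be >= 0")
  noise <- c(peak_width_sd = peak_width_sd, area_rel_noise = area_rel_noise,
             baseline_sd = baseline_sd, ms1_jitter_ppm = ms1_jitter_ppm,
             ms2_jitter_da = ms2_jitter_da, rt_jitter_sd = rt_jitter_sd)
  if (any(noise < 0)) abort("noise parameters must be >= 0")
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    abort("`seed` is mandatory for reproducibility")
  }
  structure(list(contents = contents, seed = as.integer(seed),
                 peak_width_sd = peak_width_sd,
                 area_rel_noise = area_rel_noise, baseline_sd = baseline_sd,
                 ms1_jitter_ppm = ms1_jitter_ppm,
                 ms2_jitter_da = ms2_jitter_da, rt_jitter_sd = rt_jitter_sd,
                 n_decoy_peaks = as.integer(n_decoy_peaks),
                 low_abundance_intensity = low_abundance_intensity,
                 constants = constants),
            class = "synthetic_sample_config")
}

#' Simulate one PMP-labeled polysaccharide hydrolysate sample
#'
#' Walks the forward model that the analysis pipeline inverts: true
#' content -> solution concentration (via the content constants) ->
#' peak area (via the analyte's calibration line, with multiplicative
#' noise) -> Gaussian chromatographic peak at the species' reference
#' retention time (with jitter), plus one rule-based MS2 spectrum per
#' species (high-abundance fragments at intensity 1, low at 0.1,
#' bounded m/z jitter, uniform decoy peaks over m/z 100-700). The
#' sampled trace adds Gaussian baseline noise on a regular time grid.
#'
#' @param config A [synthetic_sample_config()].
#' @param curves Named list of [calibration_curve()] objects, one per
#'   species with nonzero content.
#' @param library Species library, defaulting to [species_library()].
#' @param time_step Trace sampling interval in minutes.
#' @return A list of class `synthetic_sample`: `peaks` (tibble:
#'   species, rt, height, area, precursor_mz), `trace` (tibble: time,
#'   intensity), `spectra` (named list of [observed_spectrum()]),
#'   `truth` (tibble: species, content, concentration, area) and the
#'   `config`.
#' @export
#' @examples
#' cfg <- synthetic_sample_config(c(glucose = 100), seed = 1)
#' cv <- list(glucose = calibration_curve(2.3516e4, 1.5884e5,
#'                                        linear_range = c(199.82, 3596.80)))
#' sim <- simulate_sample(cfg, cv)
#' sim$truth
simulate_sample <- function(config, curves, library = species_library(),
                            time_step = 0.05) {
  set.seed(config$seed)
  active <- names(config$contents)[config$contents > 0]
  missing_curve <- setdiff(active, names(curves))
  if (length(missing_curve) > 0) {
    abort(paste0("no calibration curve for: ", paste(missing_curve, collapse = ", ")))
  }
  missing_rec <- setdiff(active, library$species)
  if (length(missing_rec) > 0) {
    abort(paste0("no library record for: ", paste(missing_rec, collapse = ", ")))
  }
  truth <- tibble(species = active,
                  content = unname(config$contents[active]))
  truth$concentration <- from_content(truth$content, config$constants)
  area_true <- purrr::map2_dbl(truth$species, truth$concentration, function(sp, conc) {
    cv <- curves[[sp]]
    cv$slope * conc + cv$intercept
  })
  truth$area <- area_true * (1 + rnorm(nrow(truth), 0, config$area_rel_noise))

  lib_idx <- match(truth$species, library$species)
  rt <- library$reference_rt[lib_idx] + rnorm(nrow(truth), 0, config$rt_jitter_sd)
  peaks <- tibble(
    species = truth$species,
    rt = rt,
    area = truth$area,
    height = truth$area / (config$peak_width_sd * sqrt(2 * pi)),
    precursor_mz = derivative_mz(library$class_name[lib_idx])
  )
  # additive jitter on the precursor, bounded at the configured ppm
  peaks$precursor_mz <- peaks$precursor_mz *
    (1 + runif(nrow(peaks), -1, 1) * config$ms1_jitter_ppm * 1e-6)

  time <- seq(0, 180, by = time_step)
  signal <- rep(0, length(time))
  for (i in seq_len(nrow(peaks))) {
    signal <- signal + peaks$height[i] *
      exp(-((time - peaks$rt[i])^2) / (2 * config$peak_width_sd^2))
  }
  trace <- tibble(time = time,
                  intensity = signal + rnorm(length(time), 0, config$baseline_sd))

  spectra <- purrr::map(seq_len(nrow(peaks)), function(i) {
    theo <- theoretical_spectrum(peaks$species[i])
    frag_mz <- theo$mz + runif(nrow(theo), -1, 1) * config$ms2_jitter_da
    frag_int <- ifelse(theo$abundance == "high", 1, config$low_abundance_intensity)
    if (config$n_decoy_peaks > 0) {
      frag_mz <- c(frag_mz, runif(config$n_decoy_peaks, 100, 700))
      frag_int <- c(frag_int, runif(config$n_decoy_peaks, 0.01, 0.3))
    }
    observed_spectrum(peaks$precursor_mz[i], peaks$rt[i],
                      tibble(mz = frag_mz, intensity = frag_int))
  })
  names(spectra) <- peaks$species

  structure(list(peaks = peaks, trace = trace, spectra = spectra,
                 truth = truth, config = config),
            class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf("<synthetic_sample> %d species, seed %d, %d trace points\n",
              nrow(x$peaks), x$config$seed, nrow(x$trace)))
  invisible(x)
}

#' Quantify an assigned peak table back to contents
#'
#' The inverse of the forward model in [simulate_sample()] (and of the
#' instrument workflow): peak areas are back-calculated through each
#' analyte's calibration line and converted to nmol per mg of
#' polysaccharide.
#'
#' @param peaks Data frame with `species` and `area` columns (e.g.
#'   `simulate_sample(...)$peaks` or a measured, assigned peak table).
#' @param curves Named list of [calibration_curve()] objects.
#' @param constants A [content_constants()] object.
#' @return A tibble: `species`, `area`, `concentration` (umol/L),
#'   `in_range`, `content` (nmol/mg).
#' @export
quantify_peaks <- function(peaks, curves, constants = content_constants()) {
  if (!all(c("species", "area") %in% names(peaks))) {
    abort("`peaks` needs `species` and `area` columns")
  }
  missing_curve <- setdiff(unique(peaks$species), names(curves))
  if (length(missing_curve) > 0) {
    abort(paste0("no calibration curve for: ", paste(missing_curve, collapse = ", ")))
  }
  out <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    bc <- back_calculate(peaks$area[i], curves[[peaks$species[i]]])
    tibble(species = peaks$species[i], area = peaks$area[i],
           concentration = bc$concentration, in_range = bc$in_range)
  })
  out$content <- to_content(pmax(out$concentration, 0), constants)
  out
}

#' Simulate a calibration series from a known line
#'
#' Generates `levels` standards log-spaced across the curve's linear
#' range (published ranges span up to ~18-fold, so log spacing keeps
#' the low end covered) with multiplicative Gaussian area noise.
#'
#' @param curve A [calibration_curve()] with a finite linear range.
#' @param levels Number of calibration levels (>= 3).
#' @param relative_noise Relative sd of the multiplicative area noise.
#' @param seed Integer random seed.
#' @return A tibble with `concentration` (umol/L) and `area`.
#' @export
#' @examples
#' cv <- calibration_curve(2.3516e4, 1.5884e5, linear_range = c(199.82, 3596.80))
#' simulate_calibration(cv, levels = 6, relative_noise = 0, seed = 1)
simulate_calibration <- function(curve, levels = 6, relative_noise = 0.01, seed) {
  if (levels < 3) abort("at least 3 calibration levels are required")
  if (any(!is.finite(curve$linear_range))) {
    abort("curve must carry a finite linear range")
  }
  set.seed(as.integer(seed))
  conc <- exp(seq(log(curve$linear_range[1]), log(curve$linear_range[2]),
                  length.out = levels))
  area <- (curve$slope * conc + curve$intercept) *
    (1 + rnorm(levels, 0, relative_noise))
  tibble(concentration = conc, area = area)
}

#' Simulate an L9 orthogonal experiment with planted factor effects
#'
#' Builds the [l9_design()] and generates responses from an additive
#' model: `grand_mean + effect_A[level] + effect_B[level] +
#' effect_C[level] + N(0, noise_sd)`. The empty column D carries no
#' effect, so it estimates pure noise - exactly the assumption the
#' ANOVA error term makes.
#'
#' @param effects List with numeric length-3 elements `A`, `B`, `C`
#'   (per-level effects).
#' @param noise_sd Gaussian noise sd.
#' @param seed Integer random seed.
#' @param grand_mean Baseline response.
#' @param design Optionally, a pre-built [l9_design()].
#' @return The design tibble with a `response` column and a
#'   `truth` attribute holding the generating effects.
#' @export
#' @examples
#' simulate_l9(list(A = c(0, 5, 2), B = c(0, 0, 0), C = c(0, 4, 10)),
#'             noise_sd = 0.1, seed = 7)
simulate_l9 <- function(effects, noise_sd = 0, seed, grand_mean = 0,
                        design = l9_design()) {
  if (!all(c("A", "B", "C") %in% names(effects)) ||
      !all(lengths(effects[c("A", "B", "C")]) == 3)) {
    abort("`effects` must provide length-3 vectors for A, B and C")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  set.seed(as.integer(seed))
  design$response <- grand_mean +
    effects$A[design$A] + effects$B[design$B] + effects$C[design$C] +
    rnorm(9, 0, noise_sd)
  attr(design, "truth") <- effects
  design
}

#' Write a simulation manifest
#'
#' Records the configuration and seed of a synthetic sample as a
#' two-column `key,value` CSV so a dataset on disk can be regenerated.
#'
#' @param config A [synthetic_sample_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  scalars <- c(seed = config$seed, peak_width_sd = config$peak_width_sd,
               area_rel_noise = config$area_rel_noise,
               baseline_sd = config$baseline_sd,
               ms1_jitter_ppm = config$ms1_jitter_ppm,
               ms2_jitter_da = config$ms2_jitter_da,
               rt_jitter_sd = config$rt_jitter_sd,
               n_decoy_peaks = config$n_decoy_peaks,
               low_abundance_intensity = config$low_abundance_intensity,
               content_factor = config$constants$factor)
  df <- tibble(key = c(names(scalars),
                       paste0("content.", names(config$contents))),
               value = c(unname(scalars), unname(config$contents)))
  readr::write_csv(df, path)
  invisible(path)
}
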