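# Shared fixture builders. Everything is constructed in code from the
# packaged reference tables; no binary fixtures.

# one observed spectrum per reference-table row: printed retention time,
# printed measured precursor, all detected fragment m/z at unit intensity
reference_spectra <- function(intensity = 1) {
  ref <- read_reference_ions()
  frag_cols <- reference_ion_columns()$column
  spectra <- lapply(seq_len(nrow(ref)), function(i) {
    mz <- as.numeric(ref[i, frag_cols])
    mz <- mz[!is.na(mz)]
    observed_spectrum(ref$precursor_mz[i], ref$rt_min[i],
                      data.frame(mz = mz, intensity = intensity))
  })
  names(spectra) <- ref$species
  spectra
}

# published curves plus synthetic stand-ins for the two species that
# appear in identification but have no published validation numbers
all_species_curves <- function() {
  curves <- calibration_curves()
  curves$rhamnose <- calibration_curve(2.0e4, 1.0e4,
                                       linear_range = c(1, 1000),
                                       analyte = "rhamnose")
  curves$ribose <- calibration_curve(1.8e4, 5.0e3,
                                     linear_range = c(1, 1000),
                                     analyte = "ribose")
  curves
}
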