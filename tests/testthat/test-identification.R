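test_that("a complete spectrum self-matches with score 1", {
  th <- theoretical_spectrum("glucose")
  obs <- observed_spectrum(th$precursor_mz[1], 115.3,
                           data.frame(mz = th$mz, intensity = 1))
  m <- match_spectrum(obs, "glucose")
  expect_equal(m$score, 1)
  expect_true(m$precursor_ok)
  expect_equal(m$n_matched, m$n_theoretical)
})

test_that("a reporter-only spectrum scores the reporter's weight share", {
  # expected score derived from the rule weights themselves
  th <- theoretical_spectrum("hexose")
  w <- ifelse(th$abundance == "high", 2, 1)
  expected <- 2 / sum(w)
  obs <- observed_spectrum(derivative_mz("hexose"), 115.3,
                           data.frame(mz = 175.0866, intensity = 1))
  m <- match_spectrum(obs, "hexose")
  expect_equal(m$score, expected)
  expect_lt(m$score, 0.2)
})

test_that("removing a matched peak never increases the score", {
  for (sp in c("glucose", "glucosamine", "erythrose")) {
    th <- theoretical_spectrum(sp)
    full <- observed_spectrum(th$precursor_mz[1], 100,
                              data.frame(mz = th$mz, intensity = 1))
    base <- match_spectrum(full, sp)$score
    for (drop in seq_len(nrow(th))) {
      obs <- observed_spectrum(th$precursor_mz[1], 100,
                               data.frame(mz = th$mz[-drop], intensity = 1))
      expect_lte(match_spectrum(obs, sp)$score, base)
    }
  }
})

test_that("empty or precursor-mismatched spectra give score 0, not errors", {
  obs <- observed_spectrum(511.2187, 115.3,
                           data.frame(mz = numeric(), intensity = numeric()))
  expect_equal(match_spectrum(obs, "hexose")$score, 0)
  far <- observed_spectrum(511.30, 115.3,
                           data.frame(mz = 175.0866, intensity = 1))
  m <- match_spectrum(far, "hexose")
  expect_false(m$precursor_ok)
  expect_equal(m$score, 0)
})

test_that("all 12 reference spectra are correctly identified", {
  spectra <- reference_spectra()
  res <- identify_spectra(spectra)
  expect_equal(res$species, names(spectra))
  # glucosamine is flagged by its high-abundance 372/402 ions
  expect_true(res$hexosamine_diagnostics[res$species == "glucosamine"])
  expect_false(any(res$hexosamine_diagnostics[res$species != "glucosamine"]))
})

test_that("retention time separates isobaric hexoses", {
  th <- theoretical_spectrum("galactose")
  obs <- observed_spectrum(511.2187, 130.1,
                           data.frame(mz = th$mz, intensity = 1))
  hits <- identify_spectrum(obs)
  expect_equal(hits$species[1], "galactose")
  # mannose and glucose are excluded by the 1-minute window
  expect_false(any(c("mannose", "glucose") %in% hits$species))
})

test_that("an out-of-library precursor yields an empty result", {
  obs <- observed_spectrum(999.0, 50, data.frame(mz = 175.09, intensity = 1))
  expect_identical(nrow(identify_spectrum(obs)), 0L)
})

test_that("deterministic tie-break falls back to RT deviation then name", {
  # two same-class entries straddling the observed RT: equal fragment
  # scores, so the closer reference wins; at exactly equal deviation the
  # alphabetically first species wins
  lib <- tibble::tibble(
    species = c("lyxose", "ribose"),
    class_name = "pentose",
    reference_rt = c(50, 51),
    elution_order = 1:2
  )
  th <- theoretical_spectrum("pentose")
  peaks <- data.frame(mz = th$mz, intensity = 1)
  obs <- observed_spectrum(derivative_mz("pentose"), 50.25, peaks)
  hits <- identify_spectrum(obs, library = lib)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$species[1], "lyxose")   # |50.25-50| < |50.25-51|
  # exact tie in score and RT deviation: alphabetical order decides
  mid <- observed_spectrum(derivative_mz("pentose"), 50.5, peaks)
  expect_equal(identify_spectrum(mid, library = lib)$species[1], "lyxose")
})
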