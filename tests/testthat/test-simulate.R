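test_that("the generator is reproducible and seed-sensitive", {
  curves <- all_species_curves()
  cfg <- synthetic_sample_config(c(glucose = 500, mannose = 100), seed = 7)
  a <- simulate_sample(cfg, curves)
  b <- simulate_sample(cfg, curves)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$trace, b$trace)
  expect_identical(purrr::map(a$spectra, "peaks"), purrr::map(b$spectra, "peaks"))
  cfg2 <- synthetic_sample_config(c(glucose = 500, mannose = 100), seed = 8)
  c <- simulate_sample(cfg2, curves)
  expect_false(identical(a$peaks$area, c$peaks$area))
})

test_that("zero contents give an empty peak list and a noise-only trace", {
  cfg <- synthetic_sample_config(c(glucose = 0), seed = 1)
  sim <- simulate_sample(cfg, all_species_curves())
  expect_equal(nrow(sim$peaks), 0L)
  expect_length(sim$spectra, 0L)
  expect_lt(max(abs(sim$trace$intensity)), 6 * cfg$baseline_sd)
})

test_that("missing curves or library records are reported", {
  cfg <- synthetic_sample_config(c(glucose = 10), seed = 1)
  expect_error(simulate_sample(cfg, list()), "calibration curve")
  cfg2 <- synthetic_sample_config(c(sucrose = 10), seed = 1)
  expect_error(
    simulate_sample(cfg2, list(sucrose = calibration_curve(1, 0))),
    "library record")
})

test_that("the noise-free forward model is exactly inverted by quantification", {
  curves <- calibration_curves()
  ct <- read_content_table()
  s1 <- unlist(ct[ct$sample == "S1", names(curves)])
  cfg <- synthetic_sample_config(s1, seed = 42, area_rel_noise = 0,
                                 baseline_sd = 0, ms1_jitter_ppm = 0,
                                 ms2_jitter_da = 0, rt_jitter_sd = 0)
  sim <- simulate_sample(cfg, curves)
  q <- quantify_peaks(sim$peaks, curves)
  expect_equal(setNames(q$content, q$species), s1, tolerance = 1e-12)
  # a species whose concentration exceeds its validated range is flagged
  lyx <- q[q$species == "lyxose", ]
  expect_false(lyx$in_range)
  expect_gt(lyx$concentration, curves[["lyxose"]]$linear_range[2])
})

test_that("simulated spectra with default noise identify correctly", {
  curves <- all_species_curves()
  contents <- setNames(rep(100, 12), species_library()$species)
  for (seed in c(42, 101, 202)) {
    cfg <- synthetic_sample_config(contents, seed = seed)
    sim <- simulate_sample(cfg, curves)
    res <- identify_spectra(sim$spectra)
    expect_equal(res$species, sim$peaks$species)
  }
})

test_that("simulated calibration series behave as configured", {
  cv <- calibration_curves()[["glucose"]]
  exact <- simulate_calibration(cv, levels = 6, relative_noise = 0, seed = 1)
  expect_equal(exact$area, cv$slope * exact$concentration + cv$intercept)
  expect_equal(range(exact$concentration), cv$linear_range)
  noisy <- simulate_calibration(cv, levels = 6, relative_noise = 0.01, seed = 1)
  f <- fit_calibration(noisy, concentration, area)
  expect_gt(f$r_squared, 0.999)
  expect_error(simulate_calibration(cv, levels = 2, seed = 1), "3 calibration")
})

test_that("planted L9 effects propagate into the responses", {
  flat <- simulate_l9(list(A = c(0, 0, 0), B = c(0, 0, 0), C = c(0, 0, 0)),
                      noise_sd = 0, seed = 1, grand_mean = 4)
  expect_true(all(flat$response == 4))
  d <- simulate_l9(list(A = c(0, 2.5, 5), B = c(0, 0.5, 1), C = c(0, 5, 10)),
                   noise_sd = 0, seed = 1)
  expect_equal(range_analysis(d, response)$ranges$factor, c("C", "A", "B"))
})

test_that("quantification of noisy samples stays unbiased at the percent level", {
  curves <- calibration_curves()
  ct <- read_content_table()
  s1 <- unlist(ct[ct$sample == "S1", names(curves)])
  rel_err <- vapply(1:20, function(seed) {
    cfg <- synthetic_sample_config(s1, seed = seed)
    sim <- simulate_sample(cfg, curves)
    q <- quantify_peaks(sim$peaks, curves)
    mean(abs(q$content - sim$truth$content) / sim$truth$content)
  }, numeric(1))
  expect_lt(mean(rel_err), 0.01)
})
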