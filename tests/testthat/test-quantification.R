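test_that("ordinary least squares recovers exact lines", {
  pts <- data.frame(conc = c(1, 2, 4, 8), area = c(3, 5, 9, 17))  # y = 2x + 1
  f <- fit_calibration(pts, conc, area)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  expect_equal(tidy(f)$estimate, c(1, 2))
  expect_error(fit_calibration(pts[1:2, ], conc, area), "3 points")
  same <- data.frame(conc = rep(2, 4), area = 1:4)
  expect_error(fit_calibration(same, conc, area), "vary")
})

test_that("noise-free points from every published line return the line", {
  for (cv in calibration_curves()) {
    pts <- simulate_calibration(cv, levels = 6, relative_noise = 0, seed = 1)
    f <- fit_calibration(pts, concentration, area, analyte = cv$analyte)
    expect_equal(f$slope, cv$slope, tolerance = 1e-10)
    expect_equal(f$intercept, cv$intercept, tolerance = 1e-8)
    expect_equal(f$r_squared, 1)
  }
})

test_that("1% area noise keeps the fitted slope within 3% (200 reps)", {
  cv <- calibration_curves()[["glucose"]]
  for (i in 1:200) {
    pts <- simulate_calibration(cv, levels = 6, relative_noise = 0.01,
                                seed = 1000 + i)
    f <- fit_calibration(pts, concentration, area)
    expect_lt(abs(f$slope - cv$slope) / cv$slope, 0.03)
  }
})

test_that("LOD and LOQ scale as 3 and 10 noise-to-slope ratios", {
  cv <- calibration_curve(3e4, 0, linear_range = c(1, 100))
  lim <- lod_loq(3e4 / 3, cv)
  expect_equal(lim$lod, 1)
  expect_equal(lim$loq, 10 / 3)
  expect_error(lod_loq(0, cv), "positive")
  # the 10/3 ratio ties LOQ to LOD whatever the noise
  lim2 <- lod_loq(123.4, calibration_curves()[["mannose"]])
  expect_equal(lim2$loq / lim2$lod, 10 / 3)
})

test_that("back-calculation inverts the line and flags the linear range", {
  cv <- calibration_curve(2, 1, linear_range = c(0.5, 200))
  expect_equal(back_calculate(1, cv)$concentration, 0)
  expect_equal(back_calculate(2 * 100 + 1, cv)$concentration, 100)
  glc <- calibration_curves()[["glucose"]]
  top <- back_calculate(glc$slope * 3596.80 + glc$intercept, glc)
  expect_equal(top$concentration, 3596.80)
  expect_true(top$in_range)         # the range endpoint counts as in range
  expect_false(back_calculate(glc$slope * 4000 + glc$intercept, glc)$in_range)
})

test_that("content conversion uses the workflow dilution factor and inverts", {
  expect_equal(content_constants()$factor, 2.5)
  expect_equal(to_content(0), 0)
  expect_equal(to_content(100), 250)
  expect_equal(from_content(to_content(7.3)), 7.3)
  expect_error(content_constants(sample_mass_mg = 0), "positive")
})

test_that("spike recoveries reproduce the published validation table at 2 dp", {
  rec <- read_recovery_table()
  expect_equal(recovery(rec$found, rec$original, rec$spiked), rec$recovery_pct)
  expect_equal(recovery(100, 100, 50), 0)
  expect_error(recovery(1, 1, 0), "positive")
  # invariance under common rescaling of all three amounts
  set.seed(3)
  for (s in runif(5, 0.1, 10)) {
    expect_equal(recovery(s * rec$found, s * rec$original, s * rec$spiked,
                          digits = NULL),
                 recovery(rec$found, rec$original, rec$spiked, digits = NULL))
  }
})

test_that("RSD uses the sample standard deviation over the mean", {
  expect_equal(rsd(c(5, 5, 5, 5)), 0)
  expect_equal(rsd(c(1, 2, 3)), 50)
  x <- c(10, 10, 10.2)
  brute <- sqrt(sum((x - mean(x))^2) / (length(x) - 1)) / mean(x) * 100
  expect_equal(rsd(x, digits = NULL), brute)
  expect_error(rsd(10), "2 values")
  expect_error(rsd(c(-1, 1)), "zero-mean")
})

test_that("sample summaries report honest extremes and rankings", {
  one <- data.frame(sample = "a", analyte = "glc", content = 7)
  s1 <- summarize_samples(one, sample, analyte, content)
  expect_equal(s1$overall$min_content, 7)
  expect_equal(s1$overall$max_content, 7)

  long <- contents_long(read_content_table())
  s <- summarize_samples(long, sample, analyte, content)
  # extremes of the packaged per-sample content table as printed
  expect_equal(s$overall$min_content, 15.67)
  expect_equal(s$overall$min_sample, "S9")
  expect_equal(s$overall$min_analyte, "galacturonic acid")
  expect_equal(s$overall$max_content, 3474.96)
  expect_equal(s$overall$max_sample, "S12")
  expect_equal(s$overall$max_analyte, "glucose")
  # glucose is the most abundant monosaccharide in every sample
  top <- dplyr::filter(s$rankings, rank == 1)
  expect_equal(nrow(top), 12L)
  expect_true(all(top$analyte == "glucose"))
})
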