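test_that("the L9 array is balanced and pairwise orthogonal", {
  d <- l9_design()
  for (f in c("A", "B", "C", "D")) {
    expect_equal(unname(table(d[[f]])), rep(3L, 3), ignore_attr = TRUE)
  }
  cols <- c("A", "B", "C", "D")
  for (i in 1:3) for (j in (i + 1):4) {
    expect_true(all(table(d[[cols[i]]], d[[cols[j]]]) == 1))
  }
  # level indices map to the physical hydrolysis settings
  expect_equal(d$tfa_mol_l[d$C == 3][1], 4)
  expect_equal(d$time_h[d$A == 2][1], 6)
  expect_equal(d$temperature_c[d$B == 1][1], 100)
})

test_that("constant responses give zero ranges and zero sums of squares", {
  d <- l9_design()
  d$y <- 5
  ra <- range_analysis(d, y)
  expect_true(all(ra$ranges$R == 0))
  a <- anova_l9(d, y)
  expect_true(all(a$ss == 0))
  expect_true(attr(a, "degenerate"))
})

test_that("range analysis ranks planted factor effects correctly", {
  d <- simulate_l9(list(A = c(0, 0, 0), B = c(0, 0, 0), C = c(0, 10, 20)),
                   noise_sd = 0.1, seed = 21)
  expect_equal(range_analysis(d, response)$ranges$factor[1], "C")
  # effect spans A:5, B:1, C:10 rank as C > A > B
  d2 <- simulate_l9(list(A = c(0, 2.5, 5), B = c(0, 0.5, 1), C = c(0, 5, 10)),
                    noise_sd = 0, seed = 1)
  expect_equal(range_analysis(d2, response)$ranges$factor, c("C", "A", "B"))
  expect_equal(range_analysis(d2, response)$ranges$R, c(10, 5, 1))
})

test_that("range ranking matches a brute-force group-mean oracle", {
  d <- l9_design()
  set.seed(17)
  for (rep in 1:10) {
    d$y <- rnorm(9, mean = 50, sd = 10)
    ra <- range_analysis(d, y)
    brute <- vapply(c("A", "B", "C"), function(f) {
      means <- vapply(1:3, function(l) mean(d$y[d[[f]] == l]), numeric(1))
      max(means) - min(means)
    }, numeric(1))
    expect_equal(setNames(ra$ranges$R[match(names(brute), ra$ranges$factor)],
                          names(brute)), brute)
    expect_equal(ra$ranges$factor,
                 names(sort(brute, decreasing = TRUE)))
  }
})

test_that("level sums and means satisfy K = 3k and cover all runs", {
  d <- simulate_l9(list(A = c(1, 2, 3), B = c(0, 1, 0), C = c(2, 0, 1)),
                   noise_sd = 1, seed = 5)
  ra <- range_analysis(d, response)
  expect_equal(ra$levels$K, 3 * ra$levels$k)
  per_factor <- dplyr::summarise(dplyr::group_by(ra$levels, factor),
                                 total = sum(K))
  expect_true(all(abs(per_factor$total - sum(d$response)) < 1e-10))
})

test_that("the ANOVA decomposes the total sum of squares and matches aov", {
  d <- l9_design()
  set.seed(31)
  d$y <- 10 + 2 * d$A - d$B + 3 * d$C + rnorm(9)
  a <- anova_l9(d, y)
  ss <- setNames(a$ss, a$term)
  expect_equal(ss[["A"]] + ss[["B"]] + ss[["C"]] + ss[["error"]], ss[["total"]])
  # independent oracle: stats::aov with the three factors; its 2-df
  # residual is exactly the empty-column error term
  fit <- stats::aov(y ~ factor(A) + factor(B) + factor(C), data = d)
  ref <- summary(fit)[[1]]
  expect_equal(unname(ss[c("A", "B", "C")]), ref[["Sum Sq"]][1:3])
  expect_equal(ss[["error"]], ref[["Sum Sq"]][4])
  expect_equal(a$statistic[1:3], ref[["F value"]][1:3])
  expect_equal(a$p_value[1:3], ref[["Pr(>F)"]][1:3])
})

test_that("ANOVA factor ordering by F agrees with range ordering by R", {
  d <- simulate_l9(list(A = c(0, 3, 6), B = c(0, 0.5, 1), C = c(0, 6, 12)),
                   noise_sd = 0, seed = 2)
  # break exact degeneracy of the error column with tiny jitter
  set.seed(2)
  d$response <- d$response + rnorm(9, sd = 1e-6)
  a <- anova_l9(d, response)
  f_order <- a$term[1:3][order(-a$statistic[1:3])]
  r_order <- range_analysis(d, response)$ranges$factor
  expect_equal(f_order, r_order)
})

test_that("planted effects are detected with controlled error rates", {
  hits <- matrix(NA, 120, 3)
  for (r in seq_len(nrow(hits))) {
    d <- simulate_l9(list(A = c(0, 0, 0), B = c(-20, 0, 20), C = c(0, 0, 0)),
                     noise_sd = 1, seed = 5000 + r)
    hits[r, ] <- anova_l9(d, response)$significant[1:3]
  }
  expect_gte(mean(hits[, 2]), 0.95)   # planted factor B
  expect_lte(mean(hits[, 1]), 0.10)   # null factors at the nominal level
  expect_lte(mean(hits[, 3]), 0.10)
})

test_that("optimum selection returns the level with the largest mean", {
  d <- l9_design()
  d$y <- d$A
  opt <- select_optimum(range_analysis(d, y))
  expect_equal(opt$level[opt$factor == "A"], 3L)
  expect_equal(opt$setting[opt$factor == "A"], 9)
  # planted optimum at mid time, high temperature, high acid
  d2 <- simulate_l9(list(A = c(0, 5, 1), B = c(0, 1, 4), C = c(0, 2, 6)),
                    noise_sd = 0, seed = 3)
  opt2 <- select_optimum(range_analysis(d2, response))
  expect_equal(opt2$setting[opt2$factor == "A"], 6)     # 6 h
  expect_equal(opt2$setting[opt2$factor == "B"], 120)   # 120 degC
  expect_equal(opt2$setting[opt2$factor == "C"], 4)     # 4 mol/L TFA
  # exact tie goes to the lowest level and is flagged
  d3 <- l9_design()
  d3$y <- ifelse(d3$A == 3, 1, 0)
  opt3 <- select_optimum(range_analysis(d3, y))
  expect_equal(opt3$level[opt3$factor == "B"], 1L)
  expect_true(opt3$tie[opt3$factor == "B"])
  expect_false(opt3$tie[opt3$factor == "A"])
})

test_that("malformed designs are rejected", {
  d <- l9_design()
  d$y <- 1:9
  expect_error(range_analysis(d[1:8, ], y), "9 runs")
  bad <- d
  bad$A[1] <- 2L
  expect_error(range_analysis(bad, y), "balanced")
})
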