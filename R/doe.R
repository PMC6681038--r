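#' The L9(3^4) orthogonal array for hydrolysis optimization
#'
#' Builds the canonical nine-run Taguchi array with three active
#' three-level factors - A: hydrolysis time (3, 6, 9 h), B: hydrolysis
#' temperature (100, 110, 120 degC), C: TFA concentration (2, 3, 4
#' mol/L) - and an empty fourth column D that carries no factor and
#' serves as the error estimate in the ANOVA. Every level appears
#' exactly three times per column and any two columns contain each of
#' the nine ordered level pairs exactly once.
#'
#' @param time_h,temperature_c,tfa_mol_l Physical values of the three
#'   levels of factors A, B and C.
#' @return An `l9_design` tibble with columns `run`, the level indices
#'   `A`, `B`, `C`, `D` (1-3) and the physical settings `time_h`,
#'   `temperature_c`, `tfa_mol_l`.
#' @export
#' @examples
#' l9_design()
l9_design <- function(time_h = c(3, 6, 9), temperature_c = c(100, 110, 120),
                      tfa_mol_l = c(2, 3, 4)) {
  stopifnot(length(time_h) == 3, length(temperature_c) == 3,
            length(tfa_mol_l) == 3)
  array <- matrix(c(1, 1, 1, 1,
                    1, 2, 2, 2,
                    1, 3, 3, 3,
                    2, 1, 2, 3,
                    2, 2, 3, 1,
                    2, 3, 1, 2,
                    3, 1, 3, 2,
                    3, 2, 1, 3,
                    3, 3, 2, 1), ncol = 4, byrow = TRUE)
  out <- tibble(run = 1:9,
                A = as.integer(array[, 1]), B = as.integer(array[, 2]),
                C = as.integer(array[, 3]), D = as.integer(array[, 4]),
                time_h = time_h[array[, 1]],
                temperature_c = temperature_c[array[, 2]],
                tfa_mol_l = tfa_mol_l[array[, 3]])
  attr(out, "levels") <- list(A = time_h, B = temperature_c, C = tfa_mol_l)
  class(out) <- c("l9_design", class(out))
  out
}

# factor labels used in analyses; D is the empty (error) column
l9_factors <- function(with_empty = FALSE) {
  if (with_empty) c("A", "B", "C", "D") else c("A", "B", "C")
}

check_l9 <- function(design, response) {
  cols <- l9_factors(with_empty = TRUE)
  if (!all(cols %in% names(design))) {
    abort("`design` must contain level columns A, B, C, D")
  }
  if (nrow(design) != 9) abort("an L9 design has exactly 9 runs")
  for (f in cols) {
    if (!all(sort(tabulate(design[[f]], 3)) == c(3, 3, 3))) {
      abort(paste0("column ", f, " is not balanced: each level must occur 3 times"))
    }
  }
  for (i in seq_along(cols)[-length(cols)]) {
    for (j in (i + 1):length(cols)) {
      if (any(table(design[[cols[i]]], design[[cols[j]]]) != 1)) {
        abort(paste0("columns ", cols[i], " and ", cols[j],
                     " are not orthogonal"))
      }
    }
  }
  y <- dplyr::pull(design, {{ response }})
  if (length(y) != 9 || anyNA(y)) abort("need 9 non-missing responses")
  y
}

#' Range (extreme-difference) analysis of an L9 experiment
#'
#' For each factor j and level i, computes the level sum K_ij and level
#' mean k_ij of the response over the three runs at that level, and the
#' range R_j = max_i k_ij - min_i k_ij. Factors are ranked by R
#' descending (larger spread of level means = stronger influence), ties
#' broken alphabetically.
#'
#' @param design An [l9_design()] (or any table with columns A-D) with
#'   a response column.
#' @param response Response column (tidy-eval), e.g. released
#'   monosaccharide content.
#' @param factors Factors to analyse (default A, B, C; the empty column
#'   D is excluded).
#' @return A `range_analysis` list: `levels` (tibble of factor, level,
#'   K, k, and the physical `setting` where available), `ranges`
#'   (factor, R, rank) and the response values. [tidy()] returns the
#'   `levels` table joined with R.
#' @export
#' @examples
#' d <- l9_design()
#' d$y <- 10 * d$C + rnorm(9, sd = 0.1)
#' range_analysis(d, y)$ranges
range_analysis <- function(design, response, factors = l9_factors()) {
  y <- check_l9(design, {{ response }})
  lv <- attr(design, "levels")
  levels_tbl <- purrr::map_dfr(factors, function(f) {
    idx <- design[[f]]
    tibble(factor = f, level = 1:3,
           setting = if (!is.null(lv) && f %in% names(lv)) lv[[f]] else NA_real_,
           K = as.numeric(tapply(y, idx, sum)),
           k = as.numeric(tapply(y, idx, mean)))
  })
  ranges <- levels_tbl |>
    dplyr::group_by(.data$factor) |>
    dplyr::summarise(R = max(.data$k) - min(.data$k), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$R), .data$factor)
  ranges$rank <- seq_len(nrow(ranges))
  structure(list(levels = levels_tbl, ranges = ranges, response = y),
            class = "range_analysis")
}

#' @export
print.range_analysis <- function(x, ...) {
  cat("<range_analysis> factor influence:",
      paste(x$ranges$factor, collapse = " > "), "\n")
  print(x$ranges)
  invisible(x)
}

#' @rdname range_analysis
#' @param x A `range_analysis`.
#' @param ... Unused.
#' @export
tidy.range_analysis <- function(x, ...) {
  dplyr::left_join(x$levels, x$ranges, by = "factor")
}

#' Fixed-effects ANOVA for an L9 experiment
#'
#' Per-factor sum of squares `SS_j = 3 * sum_i (k_ij - grand mean)^2`
#' with 2 degrees of freedom; the error term is the empty column D
#' (classical practice when the nine runs are unreplicated), giving F =
#' MS_factor / MS_D on (2, 2) degrees of freedom. The factor sums of
#' squares and the error term decompose the total sum of squares
#' exactly. If the empty column happens to capture zero variance the F
#' statistics are infinite and the table is flagged degenerate.
#'
#' @inheritParams range_analysis
#' @param alpha Significance level (default 0.05, i.e. 95% confidence).
#' @return A tibble with one row per factor plus an `error` and a
#'   `total` row: `term`, `ss`, `df`, `ms`, `statistic`, `p_value`,
#'   `significant`; attribute `degenerate` marks a zero error term.
#' @export
#' @examples
#' d <- l9_design()
#' d$y <- c(2, 3, 4, 3, 4, 5, 4, 5, 6) + 5 * d$B
#' anova_l9(d, y)
anova_l9 <- function(design, response, alpha = 0.05) {
  y <- check_l9(design, {{ response }})
  grand <- mean(y)
  ss <- purrr::map_dbl(l9_factors(with_empty = TRUE), function(f) {
    k <- tapply(y, design[[f]], mean)
    3 * sum((k - grand)^2)
  })
  names(ss) <- l9_factors(with_empty = TRUE)
  ss_error <- ss[["D"]]
  ms <- ss[l9_factors()] / 2
  ms_error <- ss_error / 2
  degenerate <- ms_error <= 0
  f_stat <- if (degenerate) rep(Inf, 3) else ms / ms_error
  p <- if (degenerate) rep(0, 3) else pf(f_stat, 2, 2, lower.tail = FALSE)
  out <- tibble(
    term = c(l9_factors(), "error", "total"),
    ss = unname(c(ss[l9_factors()], ss_error, sum((y - grand)^2))),
    df = c(2L, 2L, 2L, 2L, 8L),
    ms = unname(c(ms, ms_error, NA_real_)),
    statistic = unname(c(f_stat, NA_real_, NA_real_)),
    p_value = unname(c(p, NA_real_, NA_real_)),
    significant = c(p < alpha, NA, NA)
  )
  attr(out, "degenerate") <- degenerate
  out
}

#' Select the optimum factor levels from a range analysis
#'
#' For each factor, picks the level with the largest mean response
#' (hydrolysis conditions are optimized for maximal monosaccharide
#' release; pass `direction = "minimize"` to invert). Exact ties go to
#' the lowest level index and are flagged.
#'
#' @param analysis A [range_analysis()].
#' @param direction `"maximize"` (default) or `"minimize"`.
#' @return A tibble with one row per factor: `factor`, `level`,
#'   `setting` (physical value, when the design carried one), `k`
#'   (mean response at that level) and `tie`.
#' @export
#' @examples
#' d <- l9_design()
#' d$y <- d$A
#' select_optimum(range_analysis(d, y))
select_optimum <- function(analysis, direction = c("maximize", "minimize")) {
  direction <- match.arg(direction)
  analysis$levels |>
    dplyr::group_by(.data$factor) |>
    # which.max/min return the first optimum, so exact ties fall to the
    # lowest level index (rows are ordered by level within factor)
    dplyr::mutate(tie = sum(.data$k == if (direction == "maximize")
      max(.data$k) else min(.data$k)) > 1) |>
    dplyr::slice(if (direction == "maximize") which.max(.data$k)
                 else which.min(.data$k)) |>
    dplyr::ungroup() |>
    dplyr::select("factor", "level", "setting", "k", "tie")
}
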