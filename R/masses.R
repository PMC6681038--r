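#' Monoisotopic mass constants
#'
#' Single source of truth for every mass computation in the package:
#' monoisotopic atomic masses (Da) of the four elements occurring in
#' PMP-labeled monosaccharides, plus the proton mass used for
#' protonated-ion m/z. The proton mass is the hydrogen-atom mass minus
#' the electron mass; using the atom mass instead shifts every
#' quasimolecular ion by about 1 ppm at m/z 500, which is why the two
#' are kept distinct.
#'
#' @return A named list with elements `H`, `C`, `N`, `O` (atomic
#'   monoisotopic masses, Da) and `proton` (Da).
#' @export
#' @examples
#' mass_constants()$proton
mass_constants <- function() {
  list(
    H = 1.0078250319,
    C = 12.0,
    N = 14.0030740052,
    O = 15.9949146221,
    proton = 1.00727646688
  )
}

#' Elemental composition of a CHNO molecule
#'
#' Integer atom counts for carbon, hydrogen, nitrogen and oxygen.
#' Compositions support element-wise `+` and `-`; subtraction that would
#' drive any count negative is an error, since a neutral loss cannot
#' remove atoms a molecule does not have.
#'
#' @param c,h,n,o Non-negative integer atom counts.
#' @return An `elemental_composition` object.
#' @export
#' @examples
#' pmp <- comp(c = 10, h = 10, n = 2, o = 1)     # 1-phenyl-3-methyl-5-pyrazolone
#' water <- comp(h = 2, o = 1)
#' monoisotopic_mass(pmp + water)
comp <- function(c = 0, h = 0, n = 0, o = 0) {
  counts <- c(c = c, h = h, n = n, o = o)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("atom counts must be non-negative integers")
  }
  structure(as.integer(counts), names = c("c", "h", "n", "o"),
            class = "elemental_composition")
}

#' @export
Ops.elemental_composition <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "==")) {
    abort(paste0("operation `", .Generic, "` not defined for compositions"))
  }
  if (.Generic == "==") {
    return(all(unclass(e1) == unclass(e2)))
  }
  out <- get(.Generic)(unclass(e1), unclass(e2))
  if (any(out < 0)) {
    abort("composition subtraction yields a negative atom count")
  }
  structure(as.integer(out), names = c("c", "h", "n", "o"),
            class = "elemental_composition")
}

#' @export
format.elemental_composition <- function(x, ...) {
  counts <- unclass(x)
  sym <- c("C", "H", "N", "O")
  parts <- sym[counts > 0]
  nums <- counts[counts > 0]
  paste0(paste0(parts, ifelse(nums > 1, nums, "")), collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<composition>", format(x), "\n")
  invisible(x)
}

#' Exact monoisotopic mass of a composition
#'
#' Sums atom counts times the monoisotopic atomic masses from
#' [mass_constants()]. Additive over composition addition; the empty
#' composition has mass zero.
#'
#' @param x An [comp()] object.
#' @return Mass in Da (full precision; round only for display).
#' @export
#' @examples
#' monoisotopic_mass(comp(c = 6, h = 12, o = 6))  # hexose, 180.0634
monoisotopic_mass <- function(x) {
  if (!inherits(x, "elemental_composition")) {
    abort("`x` must be an elemental_composition (see `comp()`)")
  }
  m <- mass_constants()
  counts <- unclass(x)
  sum(counts * c(m$C, m$H, m$N, m$O))
}

# compositions used throughout: the label and the common neutral losses
pmp_composition <- function() comp(c = 10, h = 10, n = 2, o = 1)
water_composition <- function() comp(h = 2, o = 1)
ammonia_composition <- function() comp(h = 3, n = 1)
formaldehyde_composition <- function() comp(c = 1, h = 2, o = 1)

#' Quasimolecular ion m/z of a bis-PMP monosaccharide derivative
#'
#' PMP condenses twice onto the reducing end of a sugar with loss of one
#' water, so the neutral derivative is `sugar + 2 PMP - H2O` and the
#' observed quasimolecular ion is its protonated form:
#' `m/z = M(sugar) + 2 M(PMP) - M(H2O) + m(proton)`. For the six mass
#' classes this gives nominal ions at m/z 511 (hexose), 510
#' (hexosamine), 481 (pentose), 451 (tetrose), 495 (methylpentose) and
#' 525 (hexuronic acid). Singly protonated ions only; mono-PMP
#' derivatives and other adducts are out of scope.
#'
#' @param class_name Character vector of class names (see
#'   [sugar_classes()]).
#' @param labels Number of PMP labels; only the bis-PMP stoichiometry
#'   (`labels = 2`) is supported.
#' @return Numeric vector of theoretical `[M+H]+` m/z values (full
#'   precision; display convention is 4 decimal places, half-up).
#' @export
#' @examples
#' derivative_mz("hexose")                  # 511.2187...
#' round(derivative_mz(sugar_classes()$class_name))
derivative_mz <- function(class_name, labels = 2) {
  if (!identical(as.numeric(labels), 2)) {
    abort("only bis-PMP derivatives (`labels = 2`) are supported")
  }
  classes <- sugar_classes()
  idx <- match(class_name, classes$class_name)
  if (anyNA(idx)) {
    abort(paste0("unknown sugar class: ",
                 paste(setdiff(class_name, classes$class_name), collapse = ", ")))
  }
  m <- mass_constants()
  neutral <- classes$base_mass[idx] +
    2 * monoisotopic_mass(pmp_composition()) -
    monoisotopic_mass(water_composition())
  neutral + m$proton
}

#' Signed relative mass error in parts per million
#'
#' `(measured - theoretical) / theoretical * 1e6`. Antisymmetric in the
#' sign of the deviation; display convention is 2 decimal places.
#'
#' @param measured,theoretical Numeric m/z vectors (recycled).
#' @return Signed ppm error.
#' @export
#' @examples
#' ppm_error(510.2350, derivative_mz("hexosamine"))
ppm_error <- function(measured, theoretical) {
  check_positive(theoretical, "theoretical")
  (measured - theoretical) / theoretical * 1e6
}
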