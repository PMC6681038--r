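#' MS2 fragment rules for bis-PMP monosaccharide derivatives
#'
#' Collision-induced dissociation of protonated bis-PMP sugars follows
#' four recurring fragment groups:
#'
#' 1. dehydration of the precursor, `[M+H-H2O]+` (low abundance);
#' 2. loss of one PMP group with successive dehydration,
#'    `[M+H-PMP-k H2O]+` for k = 0..3, with ammonia instead of water
#'    losses for hexosamines (low abundance);
#' 3. loss of one PMP plus C-C cleavage of the sugar skeleton: C5-C6,
#'    C4-C5, C2-C3 and C1-C2 cleavage ions at nominal m/z 271, 241,
#'    217 (216 for hexosamine) and 187 (high abundance);
#' 4. ions retaining both PMP rings: the reporter `[PMP+H]+` at m/z
#'    175 and the C2-C3 / C3-C4 cleavage ions at nominal 373/372 and
#'    403/402 (372 and 402 only for hexosamine, where their high
#'    abundance is diagnostic).
#'
#' Each rule is either a neutral loss from the quasimolecular ion (its
#' m/z depends on the sugar class) or a fixed ion whose m/z is computed
#' once from a reference composition. Applicability encodes which
#' classes, and within a class which species, actually show the ion:
#' tetroses lack the C5-C6 and C4-C5 series, pentoses and
#' methylpentoses lack C5-C6, hexuronic acids lack the
#' `[M+H-PMP-k H2O]` series for k <= 2, and a few species-level gaps
#' (rhamnose, xylose, fucose) are carried as exclusions.
#'
#' @return A tibble with one row per rule: `rule_id`, `group` (1-4),
#'   `kind` (`"loss"` or `"fixed"`), the loss or reference-ion atom
#'   counts `c`, `h`, `n`, `o`, `mz` (fixed ions only, Da),
#'   `abundance` (`"high"` or `"low"`), `classes` (list column of
#'   applicable class names) and `exclude_species` (list column).
#' @export
#' @examples
#' fragment_rules()
fragment_rules <- function() {
  all6 <- sugar_classes()$class_name
  neutral <- setdiff(all6, "hexosamine")   # classes without the amino variants
  rule <- function(rule_id, group, kind, c = 0, h = 0, n = 0, o = 0,
                   abundance, classes, exclude_species = character()) {
    tibble(rule_id = rule_id, group = group, kind = kind,
           c = c, h = h, n = n, o = o, abundance = abundance,
           classes = list(classes), exclude_species = list(exclude_species))
  }
  out <- dplyr::bind_rows(
    # group 1: precursor dehydration
    rule("precursor_minus_water", 1L, "loss", h = 2, o = 1, abundance = "low",
         classes = all6, exclude_species = "rhamnose"),
    # group 2: single PMP loss with water (or ammonia) losses
    rule("loss_pmp", 2L, "loss", c = 10, h = 10, n = 2, o = 1, abundance = "low",
         classes = c("hexose", "hexosamine", "pentose", "tetrose", "methylpentose"),
         exclude_species = "xylose"),
    rule("loss_pmp_water", 2L, "loss", c = 10, h = 12, n = 2, o = 2, abundance = "low",
         classes = c("hexose", "pentose", "tetrose", "methylpentose"),
         exclude_species = "fucose"),
    rule("loss_pmp_2water", 2L, "loss", c = 10, h = 14, n = 2, o = 3, abundance = "low",
         classes = c("hexose", "pentose", "tetrose", "methylpentose")),
    rule("loss_pmp_3water", 2L, "loss", c = 10, h = 16, n = 2, o = 4, abundance = "low",
         classes = c("hexose", "pentose", "methylpentose", "hexuronic_acid")),
    rule("loss_pmp_ammonia", 2L, "loss", c = 10, h = 13, n = 3, o = 1, abundance = "low",
         classes = "hexosamine"),
    rule("loss_pmp_ammonia_water", 2L, "loss", c = 10, h = 15, n = 3, o = 2,
         abundance = "low", classes = "hexosamine"),
    rule("loss_pmp_ammonia_2water", 2L, "loss", c = 10, h = 17, n = 3, o = 3,
         abundance = "low", classes = "hexosamine"),
    # group 3: PMP loss + C-C skeleton cleavage (high abundance)
    rule("c5c6_cleavage", 3L, "fixed", c = 15, h = 14, n = 2, o = 3, abundance = "high",
         classes = c("hexose", "hexuronic_acid")),
    rule("c5c6_cleavage_amino", 3L, "loss", c = 11, h = 17, n = 3, o = 3,
         abundance = "high", classes = "hexosamine"),       # PMP + CH2O + NH3 + H2O
    rule("c4c5_cleavage", 3L, "fixed", c = 14, h = 12, n = 2, o = 2, abundance = "high",
         classes = c("hexose", "pentose", "methylpentose", "hexuronic_acid")),
    rule("c4c5_cleavage_amino", 3L, "loss", c = 12, h = 19, n = 3, o = 4,
         abundance = "high", classes = "hexosamine"),       # PMP + 2CH2O + NH3 + H2O
    rule("c2c3_cleavage", 3L, "fixed", c = 12, h = 12, n = 2, o = 2, abundance = "high",
         classes = neutral),
    rule("c2c3_cleavage_amino", 3L, "fixed", c = 12, h = 13, n = 3, o = 1,
         abundance = "high", classes = "hexosamine"),
    rule("c1c2_cleavage", 3L, "fixed", c = 11, h = 10, n = 2, o = 1, abundance = "high",
         classes = all6),
    # group 4: ions retaining both PMP rings
    rule("c2c3_cleavage_water", 4L, "fixed", c = 22, h = 20, n = 4, o = 2,
         abundance = "high", classes = neutral),
    rule("c2c3_cleavage_water_amino", 4L, "fixed", c = 22, h = 21, n = 5, o = 1,
         abundance = "high", classes = "hexosamine"),       # diagnostic, nominal 372
    rule("c3c4_cleavage_water", 4L, "fixed", c = 23, h = 22, n = 4, o = 3,
         abundance = "low", classes = c("hexose", "methylpentose"),
         exclude_species = "rhamnose"),
    rule("c3c4_cleavage_water_amino", 4L, "fixed", c = 23, h = 23, n = 5, o = 2,
         abundance = "high", classes = "hexosamine"),       # diagnostic, nominal 402
    rule("pmp_reporter", 4L, "fixed", c = 10, h = 10, n = 2, o = 1,
         abundance = "high", classes = all6)
  )
  proton <- mass_constants()$proton
  comp_mass <- purrr::pmap_dbl(out[, c("c", "h", "n", "o")],
                               function(c, h, n, o) monoisotopic_mass(comp(c, h, n, o)))
  out$mz <- ifelse(out$kind == "fixed", comp_mass + proton, NA_real_)
  out
}

# rule_ids whose high abundance flags hexosamine (glucosamine) presence
hexosamine_diagnostic_rules <- function() {
  c("c2c3_cleavage_water_amino", "c3c4_cleavage_water_amino")
}

#' Theoretical MS2 spectrum of a PMP-labeled sugar
#'
#' Applies every applicable [fragment_rules()] entry to a sugar class or
#' to one of the 12 library species. Loss rules subtract the neutral
#' loss mass from the class quasimolecular ion; fixed-ion rules emit
#' their reference m/z. For a named species the species-level rule
#' exclusions apply; for a bare class name only class-level
#' applicability is used.
#'
#' @param target A class name from [sugar_classes()] or a species name
#'   from [species_library()].
#' @param rules Rule set, defaulting to [fragment_rules()].
#' @return A tibble sorted by `mz` with columns `mz`, `rule_id`,
#'   `group`, `abundance`, plus `target`, `class_name` and
#'   `precursor_mz`.
#' @export
#' @examples
#' theoretical_spectrum("glucose")
#' theoretical_spectrum("hexuronic_acid")
theoretical_spectrum <- function(target, rules = fragment_rules()) {
  lib <- species_library()
  if (target %in% lib$species) {
    species <- target
    class_name <- lib$class_name[lib$species == target]
  } else if (target %in% sugar_classes()$class_name) {
    species <- NA_character_
    class_name <- target
  } else {
    abort(paste0("`", target, "` is neither a sugar class nor a library species"))
  }
  keep <- purrr::map_lgl(seq_len(nrow(rules)), function(i) {
    ok <- class_name %in% rules$classes[[i]]
    if (ok && !is.na(species)) ok <- !(species %in% rules$exclude_species[[i]])
    ok
  })
  app <- rules[keep, ]
  prec <- derivative_mz(class_name)
  loss_mass <- purrr::pmap_dbl(app[, c("c", "h", "n", "o")],
                               function(c, h, n, o) monoisotopic_mass(comp(c, h, n, o)))
  out <- tibble(
    target = target,
    class_name = class_name,
    precursor_mz = prec,
    rule_id = app$rule_id,
    group = app$group,
    abundance = app$abundance,
    mz = ifelse(app$kind == "fixed", app$mz, prec - loss_mass)
  )
  stopifnot(all(out$mz > 0))
  dplyr::arrange(out, .data$mz)
}
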