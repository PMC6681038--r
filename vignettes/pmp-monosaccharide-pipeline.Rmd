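---
title: "Methods: PMP-labeled monosaccharide analysis with pmpms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PMP-labeled monosaccharide analysis with pmpms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmpms)
```

`pmpms` models the data-analysis half of a monosaccharide composition
workflow: polysaccharide is hydrolyzed with trifluoroacetic acid (TFA),
the released reducing sugars are labeled with
1-phenyl-3-methyl-5-pyrazolone (PMP), and the bis-PMP derivatives are
separated by reversed-phase LC and detected by ESI–MS with data-dependent
MS². This vignette documents the models, the defaults, and the design
decisions, in that order. All empirical claims below are the ones
exercised by the package's own test suite and acceptance script.

## The mass model

PMP condenses twice onto the reducing end of a sugar, releasing one
water, so the neutral derivative is `sugar + 2 PMP − H₂O` and the
observed quasimolecular ion is

$$ m/z_{[M+H]^+} = M(\mathrm{sugar}) + 2\,M(\mathrm{PMP}) - M(\mathrm{H_2O}) + m_p $$

with $m_p$ the proton mass. Three choices matter:

- **Atomic masses.** CODATA/IUPAC monoisotopic values at ≥ 6 decimals
  (H 1.0078250, C 12 exactly, N 14.0030740, O 15.9949146; proton
  1.0072765), held in one place (`mass_constants()`) so every m/z in
  the package derives from the same constants.
- **Proton, not hydrogen atom.** Protonation adds a proton
  ($m_p = M(\mathrm{H}) - m_e$), not a hydrogen atom. Using the atom
  mass would shift every ion by ≈ 1 ppm at *m/z* 500 and the
  4-decimal reference value for hexose (511.2187) would not be
  reproduced.
- **Stoichiometry fixed at bis-PMP.** Mono-PMP derivatives, multiple
  charging, adducts other than H⁺ and isotope envelopes are out of
  scope: quantitative PMP derivatization drives the reaction to the
  bis-labeled product, and the reference data contain only singly
  protonated bis-PMP ions.

Internally all masses are double precision; rounding (half away from
zero, `round_half_up()`) is applied only at reporting time — 4 decimals
for m/z, 2 for ppm and percentages. The nominal class ions (511, 510,
481, 451, 495, 525) are the [M+H]⁺ values rounded to integers.

Recomputing the ppm error of every reference precursor against these
constants reproduces the tabulated errors within 0.1 ppm. Exact
equality is not attainable: the tabulated measured m/z are themselves
rounded to 4 decimals (±0.0001 Da ≈ ±0.2 ppm at *m/z* 500), and the
instrument software's formula-predictor constants are unknown. The
tests therefore assert agreement within 0.1 ppm and do not chase the
last digit.

## Fragment rules and identification

MS² spectra of bis-PMP sugars are generated from a small rule set
(`fragment_rules()`) rather than stored spectra. Rules are of two
kinds:

- **Neutral losses** from the class quasimolecular ion:
  `[M+H−H₂O]⁺`, and `[M+H−PMP−k·H₂O]⁺` for k = 0…3. For hexosamines
  the water losses after PMP loss are replaced by ammonia-containing
  losses (−NH₃, −NH₃−H₂O, −NH₃−2H₂O, and the C5–C6/C4–C5 cleavage
  losses −CH₂O−NH₃−H₂O and −2CH₂O−NH₃−H₂O).
- **Fixed ions** whose m/z does not depend on the sugar class: the
  PMP reporter and the C–C cleavage ions that retain one or both PMP
  rings. The tabulated reference data give these only as nominal
  assignments plus measured values scattered over tens of mDa, so
  each fixed ion is assigned one plausible composition, documented
  here, and its exact mass computed from `mass_constants()`:

  | nominal | composition (protonated) | exact m/z |
  |---------|--------------------------|-----------|
  | 175 | C₁₀H₁₀N₂O·H⁺ (PMP+H) | 175.0866 |
  | 187 | C₁₁H₁₀N₂O·H⁺ | 187.0866 |
  | 217 / 216 | C₁₂H₁₂N₂O₂·H⁺ / C₁₂H₁₃N₃O·H⁺ | 217.0972 / 216.1131 |
  | 241 | C₁₄H₁₂N₂O₂·H⁺ | 241.0972 |
  | 271 | C₁₅H₁₄N₂O₃·H⁺ | 271.1077 |
  | 373 / 372 | C₂₂H₂₀N₄O₂·H⁺ / C₂₂H₂₁N₅O·H⁺ | 373.1659 / 372.1819 |
  | 403 / 402 | C₂₃H₂₂N₄O₃·H⁺ / C₂₃H₂₃N₅O₂·H⁺ | 403.1765 / 402.1925 |

  Each reference value lies within 0.05 Da of its assigned ion, so at
  the MS² matching tolerance the residual composition ambiguity is
  immaterial; the rule set does not arbitrate the cleavage chemistry
  beyond these assignments (the *m/z* 187 ion in particular is treated
  as a universal fixed ion even though hexosamine fragmentation offers
  an alternative loss route to the same mass).

**Applicability** encodes which ions are actually observed: tetroses
lack the C5–C6 and C4–C5 series (the skeleton is too short), pentoses
and methylpentoses lack C5–C6, hexuronic acids lack `[M+H−PMP−k·H₂O]`
for k ≤ 2. Three gaps in the reference data are species-specific
rather than class-wide — rhamnose lacks the precursor dehydration and
the 403 ion that fucose shows, xylose lacks `[M+H−PMP]⁺`, fucose lacks
`[M+H−PMP−H₂O]⁺` — so rules carry species-level exclusions on top of
class applicability. A generated spectrum for a *species* reproduces
the detected/not-detected pattern of the reference table cell for
cell; a spectrum for a bare *class* applies class-level rules only.

**Matching and scoring.** The precursor must match the class ion
within 10 ppm (TOF-level MS1 accuracy; all reference precursor errors
are ≤ 4.8 ppm). Fragments match within ±0.05 Da (ion-trap MS²; the
reference MS² deviations reach tens of mDa). The score is the matched
fraction of rule weights — 2 for expected-high-abundance rules, 1 for
low — so it is 1 for a complete match, below 0.2 for a bare PMP
reporter, and monotone: removing a matched peak never raises it.
Abundance labels follow the observed fragment behavior: the skeleton
cleavage ions and the reporter are high; dehydration and PMP-loss
series are low; for hexosamine the 372 and 402 ions are high — their
high abundance *is* the glucosamine diagnostic, flagged when both
match with relative intensity ≥ 0.2 (the generic 403 ion of other
classes stays low/weak).

**Identification** filters the 12-species library by precursor class,
then by |RT − reference RT| ≤ 1.0 min. The window sits below half the
closest same-class retention gap, so isobaric sugars
(mannose/glucose/galactose; lyxose/ribose/xylose; rhamnose/fucose;
glucuronic/galacturonic acid) resolve uniquely at reference retention
times. Ties break deterministically: fragment score, then smaller RT
deviation, then alphabetical order. No candidate inside both
tolerances returns an empty table, not an error.

One inconsistency in the reference data is recorded rather than
resolved: the prose elution order lists rhamnose before ribose before
lyxose, while the tabulated retention times give
lyxose (40.298) < rhamnose (47.701) < ribose (48.832). The library
follows the tabulated times, which also match the numbered peaks of
the reference chromatogram.

## Calibration, limits, contents, validation

Calibration is unweighted ordinary least squares of peak area on
concentration (µmol/L); published curves report plain linear fits with
r² only, so no 1/x weighting is applied. r² is the squared Pearson
correlation of areas with fitted values. LOD and LOQ are the
concentrations whose signal reaches 3 and 10 times the baseline noise
SD through the slope: LOD = 3σ/slope, LOQ = 10σ/slope, hence
LOQ = (10/3)·LOD. The packaged validation table confirms this ratio:
nine of ten analytes reproduce the printed LOQ exactly at 2 decimals
from (10/3) × printed LOD; glucosamine differs by 0.01 (2.77 vs 2.76)
because the printed LOD is itself rounded — the tests assert exact
agreement for at least nine analytes and one-unit-in-the-last-place
agreement for all ten, the precision the printed inputs support.

Concentration converts to content (nmol per mg polysaccharide) by the
workflow dilution factor: a `sample_mass_mg` portion (default 20 mg)
is hydrolyzed and dissolved in `dissolution_volume_ml` (5 mL); an
`aliquot_volume_ml` aliquot (0.1 mL) is derivatized and brought to
`final_volume_ml` (1 mL). The defaults give factor 2.5; the constants
are configuration (`content_constants()`) because different labs scale
the workflow differently. Recovery is (found − original)/spiked ×
100%, invariant under common rescaling; RSD uses the sample (n−1)
standard deviation, appropriate for the n = 3–6 replicate series the
statistic is used on. Reported percentages and limits round half-up to
2 decimals.

`summarize_samples()` reports the *computed* extremes of a content
table. On the packaged 12-sample table these are 15.67 nmol/mg (S9,
galacturonic acid) and 3474.96 nmol/mg (S12, glucose); the prose
summary accompanying the published table states 20.88–3329.49, which
does not match the table as printed (those are the S9 glucuronic-acid
and S6 glucose cells). The package reports what the data contain; the
discrepancy is a known inconsistency of the source tables, and the
glucose-is-always-dominant ranking holds either way.

## The L9(3⁴) analysis

`l9_design()` builds the canonical nine-run array (runs 111, 122, 133,
212, 223, 231, 313, 321, 332 over columns A–D); every level appears
three times per column and any two columns contain each ordered level
pair exactly once. Row order is the textbook convention — all
statistics depend only on orthogonality, not on run order. Factor A is
hydrolysis time (3/6/9 h), B temperature (100/110/120 °C), C TFA
concentration (2/3/4 mol/L); D is left empty.

Range analysis computes level sums K, level means k and ranges
R = max k − min k per factor and ranks factors by R. The ANOVA uses
SS = 3·Σ(k − grand mean)² per factor with 2 df and takes the empty
column D as the error term — the classical choice when the nine runs
are unreplicated; with no factor assigned, D's 2-df sum of squares
estimates pure noise, and `stats::aov` on A+B+C yields the identical
residual (the tests check this equivalence). F tests use (2, 2) df at
95% confidence. A zero error term (e.g. noise-free synthetic
responses) makes F infinite; the table is then flagged degenerate
rather than silently reported. Optimum selection takes, per factor,
the level with the largest mean response (hydrolysis is optimized for
maximal release); exact ties go to the lowest level index and are
flagged.

The published per-sugar range and ANOVA values themselves are not
reproducible here — the underlying nine-run response tables live in an
appendix that is not part of the available data — so the analysis is
validated by properties instead: agreement with a brute-force
group-mean oracle, exact SS decomposition, and planted-effect
simulations (a factor with level effects spanning 40 units against
noise SD 1 is detected in ≥ 95% of 500 replicates while null factors
stay at the nominal 5–10% false-positive rate).

## The synthetic generator

`simulate_sample()` runs the forward model the pipeline inverts:

content → concentration (÷ 2.5) → area (calibration line, × (1 + ε),
ε ~ N(0, 1%)) → Gaussian peak (SD 0.2 min) at the reference RT +
N(0, 0.1 min) jitter → trace on a 0–180 min grid with additive
N(0, σ_baseline) noise; plus one MS² spectrum per species with
high-abundance fragments at relative intensity 1, low at 0.1, bounded
uniform m/z jitter (±5 ppm MS1, ±0.02 Da MS²), and five uniform decoy
peaks over the *m/z* 100–700 scan range.

Defaults were chosen once to emulate the reference conditions: the 1%
area noise matches the order of the published precision/repeatability
RSDs (0.4–1.4%); the jitters sit inside the matching tolerances as
real calibrant-corrected data would; peak width and scan range follow
the reference chromatography and MS settings. The generator is
deliberately idealized — it does not simulate profile-mode data,
isotope envelopes, co-elution, detector saturation, retention drift
with gradient age, or matrix-dependent ionization suppression. Passing
round-trip tests therefore demonstrate that the *computational*
pipeline is self-consistent and unbiased under its stated noise model
(noise-free round trips are exact; with default noise the mean
relative quantification error over 100 seeds is below 1%), not that
the method performs at that level on real extracts.

Every simulation takes a mandatory seed; the same seed gives
byte-identical output. Problem sizes used by the test suite — 200
calibration replicates, 500 L9 replicates, 100 round-trip seeds, 12
species — keep the full suite in the low minutes on one CPU while
leaving Monte-Carlo rates with comfortable margins.

## Interfaces and limitations

Tables move as comma-separated UTF-8 text with a header row and "."
decimals; typographic minus/dash characters are normalized on ingest
and a bare "-" cell means "not detected" (NA). MS² spectra use an
MGF-style dialect (`BEGIN IONS`/`PEPMASS`/`RTINSECONDS`/peak pairs).
Every writer's output is readable by its reader with value equality.
The package exposes its functionality as a data-frame-first R API
(with `tidy()`/`glance()`/`autoplot()` methods) rather than a shell
executable; `scripts/acceptance.R` is the scripted entry point that
re-derives the headline numbers.

Known limitations: no peak detection/integration from raw
chromatograms (areas are inputs); no de novo composition inference for
sugar classes outside the six supported ones; no MS³; rhamnose and
ribose are identifiable but carry no published calibration/validation
numbers, so quantitative work on them requires user-supplied curves
(the test suite uses clearly labeled synthetic stand-ins); and the
fixed-ion compositions above are documented assignments, adequate at
±0.05 Da but not authoritative chemistry.
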