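Package: pmpms
Title: Monosaccharide Composition Analysis of Polysaccharides by
    PMP-Labeling LC-MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for qualitative and quantitative monosaccharide
    composition analysis of polysaccharide hydrolysates labeled with
    1-phenyl-3-methyl-5-pyrazolone (PMP) and measured by LC-ESI-MS.
    Computes exact monoisotopic masses and ppm errors of bis-PMP sugar
    derivatives, generates rule-based theoretical MS2 spectra
    (neutral-loss and reporter-ion rules) for six monosaccharide mass
    classes, identifies species from precursor mass, retention time and
    diagnostic fragments, fits calibration curves with LOD/LOQ,
    converts concentrations to per-milligram contents with spike
    recovery and RSD validation statistics, and analyses L9(3^4)
    orthogonal hydrolysis-optimization designs (range analysis and
    ANOVA). A seeded synthetic data generator emulates chromatograms,
    MS2 spectra, calibration sets and orthogonal response tables so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
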