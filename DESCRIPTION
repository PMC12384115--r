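Package: carotidnirs
Title: Simulation and Equivalence Analysis of Wearable NIRS Carotid Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous-wave near-infrared spectroscopy (NIRS) of the
    radial and carotid arteries: a diffusion-approximation forward model for
    semi-infinite tissue, a synthetic cohort generator that emulates a
    five-segment breath-hold / deep-breathing protocol at four patch locations,
    modified Beer-Lambert reconstruction of oxy- and deoxyhemoglobin changes and
    tissue oxygen saturation, extraction of the six breath-protocol parameters of
    interest with signal-to-noise based trial selection, and a nonparametric
    equivalence-testing battery (continuity-corrected Wilcoxon two one-sided
    tests with Hodges-Lehmann estimates, Kendall rank correlations,
    Kruskal-Wallis effect sizes, and paired-TOST sample-size calculation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
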