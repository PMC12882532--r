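Package: capsheet
Title: Quantification of Calcium-Phosphate Sheet-Aggregates in Cryo-EM Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of calcium-phosphate sheet-aggregates
    imaged by cryo-electron microscopy. Implements adaptive-threshold
    measurement of aggregate areas from micrographs and label masks with
    nonparametric group comparison, radial-profile analysis of low-dose
    selected-area electron diffraction (LDSAED) with background-ratio
    correction and detection of the broad octacalcium-phosphate-like
    diffraction band near 2.5-3.2 Angstrom d-spacing, Fisher's exact
    analysis of intracellular/extracellular marker colocalization counts,
    and seeded synthetic-data generators with ground truth for validating
    every stage. Reads and writes MRC2014 and TIFF images and CSV tables.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
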