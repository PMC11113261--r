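Package: nucleoclock
Title: Cell-Free DNA Nucleosomics: Fragmentomics, Nucleosome Repeat
    Length and Aging Clocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of aligned cell-free DNA (cfDNA) fragments for
    nucleosome-level aging signatures.  Computes fragment-size
    distributions, phasograms (histograms of pairwise distances between
    fragment centres), nucleosome repeat length (NRL) estimates by peak
    regression, 100-bp binned occupancy tracks with differential-region
    discovery and PCA cohort stratification, and linear-regression age
    predictors and age-group classifiers built on fragment-size or
    nucleosome-distance features.  Includes a synthetic cfDNA cohort
    simulator with age-linked nucleosome spacing and fragment-mixture
    drift, so every pipeline stage can be validated against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
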