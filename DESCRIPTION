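Package: cofrac
Title: Co-Fractionation Mass Spectrometry Interaction Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for size-exclusion chromatography
    coupled to mass spectrometry (SEC-MS) co-fractionation experiments.
    Builds protein elution profiles from peptide-level quantities using a
    sibling-peptide correlation strategy, scores candidate protein pairs with
    a 147-value co-elution descriptor and a fully connected neural network,
    controls the false-discovery rate of predicted interactions by
    target-decoy competition, calibrates fraction indices to apparent
    molecular weights, scores differential elution between conditions, and
    computes interactome network statistics. Ships a synthetic
    co-fractionation data generator with planted protein complexes so every
    stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    signal,
    igraph,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pracma,
    jsonlite,
    optparse,
    Biostrings
Config/testthat/edition: 3
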