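Package: segrobust
Title: Interobserver Segmentation Variability and Radiomic Feature Robustness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify how interobserver and interdisciplinary tumor
    segmentation variability propagates into CT radiomics. Simulates
    multi-observer, two-discipline delineation cohorts on low-contrast
    phantom volumes, builds per-patient consensus segmentations with the
    STAPLE expectation-maximization algorithm, grades observer agreement
    with the Dice similarity coefficient, extracts a 1277-feature radiomic
    panel (first order, shape, GLCM, GLRLM, GLSZM, NGTDM/NGLDM and
    intensity-volume histogram features on the original,
    Laplacian-of-Gaussian filtered and 3D wavelet subband images), and
    scores per-feature robustness with the two-way random-effects
    single-measurement intraclass correlation ICC(2,1), split by observer
    discipline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
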