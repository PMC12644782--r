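Package: cogmsm
Title: Multistate Markov Models for Cognitive Ageing Cohorts with Blood
    Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Panel-observed, interval-censored four-state Markov models of
    cognitive ageing (normal cognition, mild cognitive impairment, dementia,
    death) with Gompertz age-dependent transition intensities, censored state
    sets, exact death times and dementia-at-death intervals. Includes
    neuropsychological staging rules (MCI/CIND), blood-biomarker preparation
    (below-LOD imputation, z-scoring, restricted cubic splines, predefined
    cut-offs), bootstrap Youden-index cut-off derivation,
    inverse-probability-of-attrition weighting, and a synthetic cohort
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
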