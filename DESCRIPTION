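Package: snpblup
Title: Pedigree and SNP Relationship Matrices for Longitudinal Breeding Value Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares pedigree-based and SNP-based genetic covariance matrices
    for predicting breeding values of non-phenotyped animals at an unobserved
    time point. Builds the additive (numerator) relationship matrix from
    pedigree by the tabular method, marker-based relatedness by the Loiselle
    moment estimator and by averaging local allele-sharing matrices along a
    chromosome, estimates per-time-point variance components by EM-REML under
    an animal model, solves the mixed model equations for breeding values of
    all animals, extrapolates each animal's breeding value trajectory to a
    later time by quadratic regression, and evaluates predictions against
    true breeding values (accuracy, dispersion bias, top-N overlap,
    within-full-sib-family spread). Includes a gene-dropping simulator that
    generates multi-generation populations with QTL effects on growth-curve
    coefficients for end-to-end testing.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
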