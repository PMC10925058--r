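Package: perfvol
Title: Coupling of Regional Pulmonary Perfusion and Blood Volume from Dynamic PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the coupling between regional pulmonary
    perfusion (Q) and intravascular blood volume fraction (Fb) measured with
    dynamic positron emission tomography. Provides a seeded synthetic
    lung-phantom and tracer simulator (Sokoloff three-compartment 18F-FDG
    kinetics, 13NN-saline breathhold curves with shunt), estimation of the
    regional blood fraction by bounded nonlinear least squares, plateau/peak
    perfusion estimation, the tissue-fraction normalization algebra
    (F_tis, F_tis,n, Q_n, F_bn, and cardiac-output / blood-volume adjusted
    longitudinal quantities), a two-sample multivariate kernel-density test
    with unconstrained plug-in bandwidths, a six-model least-squares zoo
    ranked by the Bayesian information criterion, likelihood-ratio tests of
    nested models, stratified piecewise-linear fits, and an end-to-end seeded
    analysis pipeline with tabular report outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cli,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
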