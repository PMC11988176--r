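Package: gpcomp
Title: Genomic Prediction Model Comparison for Pedigreed Livestock Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-driven comparison of genomic prediction models for
    quantitative traits in pedigreed livestock populations. Provides a
    gene-dropping population simulator with configurable genetic
    architectures, marker quality control and density panels, fixed-effect
    phenotype correction, pedigree (A), genomic (VanRaden G) and single-step
    (H inverse) relationship matrices, AI-REML variance-component and
    heritability estimation, GBLUP/ssGBLUP/SNP-BLUP mixed-model solvers, a
    Gibbs-sampling engine for BayesA, BayesB, BayesC, Bayesian LASSO and
    BayesR marker-effect models, and n-fold cross-validated accuracy and
    dispersion-bias evaluation over models, fold counts, variant classes and
    marker densities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
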