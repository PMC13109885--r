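Package: gpeval
Title: Genomic Prediction Models and Cross-Validation for Poultry Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genomic evaluation of quantitative traits in
    pedigreed livestock populations. Implements pedigree (A), genomic (G),
    blended (Gw) and single-step (H inverse) relationship matrices,
    EM-REML variance component estimation, Henderson mixed-model solvers
    for ABLUP/GBLUP/ssGBLUP/WGBLUP, the iterative SNP-weighting procedure
    of weighted single-step GWAS, kernel ridge regression and other
    machine-learning predictors with internal cross-validated grid search,
    marker quality control with Hardy-Weinberg exact testing, LD pruning,
    principal-component covariates, a repeated k-fold cross-validation
    harness (accuracy, dispersion bias, MSE, MAE, Bland-Altman agreement),
    and a forward gene-dropping simulator of pedigrees, LD-structured
    genotypes and heritable traits for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
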