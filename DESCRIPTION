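Package: prsgxe
Title: Gene-Environment Interaction Analysis of Polygenic Risk and Air-Pollution Trends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how long-term air-pollution trends and polygenic
    susceptibility jointly relate to type 2 diabetes in cohort data.
    Implements per-participant exposure-trend slopes from annual pollutant
    concentrations, genotype and sample quality control, a
    clumping-and-thresholding polygenic risk score with threshold selection by
    delta-AUC, crude and covariate-adjusted logistic odds-ratio models, and
    additive (relative excess risk due to interaction, with percentile
    bootstrap confidence intervals) and multiplicative interaction statistics.
    A synthetic-data generator with known ground truth (LD-block genotypes,
    noisy external GWAS summary statistics, trended exposure series, and
    outcomes from a logistic model with a gene-environment product term)
    makes the full pipeline testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
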