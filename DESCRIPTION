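Package: regmr
Title: Regional Association, Meta-Analysis, Fine-Mapping and Wald-Ratio
    Mendelian Randomization for Hormone-Driven Cancer Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the classical single-region candidate-gene workflow
    linking a genetic variant, an intermediate biomarker and disease risk:
    per-allele logistic trend tests and linear hormone-level regressions with
    optional cluster-robust (sandwich) standard errors, fixed-effects
    inverse-variance meta-analysis with Cochran's Q and the I-squared
    heterogeneity statistic, conditional association scans and
    likelihood-ratio candidate-causal-variant sets filtered by linkage
    disequilibrium r-squared, case-distribution quartile stratification with
    one-degree-of-freedom gene-environment interaction tests, and Wald-ratio
    Mendelian randomization comparing the disease odds ratio predicted from a
    variant's effect on log estradiol with the directly observed odds ratio.
    Includes a seeded synthetic-data generator (Markov-chain linkage
    disequilibrium haplotypes, retrospective case-control sampling, hormone
    phenotypes with batch, study and familial-cluster structure) so the whole
    pipeline can be exercised and tested without access to individual-level
    consortium data, plus VCF/TSV input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    sandwich,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
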