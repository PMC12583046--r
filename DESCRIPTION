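Package: ssfaers
Title: Disproportionality Signal Detection for Drug-Associated Serotonin
    Syndrome in Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of drug-associated
    serotonin syndrome in elderly patients using FAERS-style quarterly
    ASCII extracts. Provides case ingestion and deduplication, drug-name
    normalization with ATC first-level classification, four-algorithm
    disproportionality analysis (reporting odds ratio, proportional
    reporting ratio with chi-square, Bayesian confidence propagation
    neural network information component, and multi-item gamma-Poisson
    shrinker), volcano-plot statistics from Fisher's exact test with
    Bonferroni correction, time-to-onset summaries with rank-based group
    comparisons, Table-1 style descriptive summaries, and a synthetic
    spontaneous-report generator with planted ground truth for validating
    the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
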