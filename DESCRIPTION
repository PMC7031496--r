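Package: culpritScreen
Title: Pan-Cancer Screening for Transcriptional Correlates of T-Cell-Cold Tumors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies CD8+ T-cell infiltration in bulk tumor transcriptomes
    with small metagene signatures (geometric mean of log2 expression), ranks
    every gene within every tumor group for association with the T-cell-cold
    state by two parallel statistics (low-vs-high tertile log fold change with
    an empirical-Bayes moderated t, and Spearman correlation with the signature
    score), and selects recurrently top-ranked candidate regulators across
    tumor groups by median-percentile-rank and Bonferroni-corrected exact
    binomial recurrence criteria. Downstream modules characterize mutually
    exclusive expression programs among selected genes via all-pairs Fisher
    log2 odds ratios on binarized expression, and test derived signatures
    against immunotherapy response (quartile Fisher tests) and overall survival
    (Kaplan-Meier, log-rank). Seeded synthetic-data generators with planted
    ground truth provide a test surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
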