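Package: drugsyn
Title: Gene Set-Based Prediction of Drug Combination Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts synergistic drug combinations from per-drug gene
    expression profiles. For each drug treatment a delta z-score profile
    versus the vehicle (DMSO) control is computed, gene sets are scored by
    a mean delta z-score enrichment statistic with permutation-based
    empirical significance and Benjamini-Hochberg adjustment, and every
    unordered drug pair receives three similarity scores (co-gene, co-GS,
    co-gene/GS) that rank pairs by predicted synergy. Rankings are
    evaluated against an excess-over-Bliss gold standard with the
    probabilistic concordance index (PC-index), signal-to-noise-ratio
    classification, ROC/AUC and precision analyses. Includes a
    kappa-statistic redundancy filter for gene-set collections and a
    synthetic-data generator with planted pathway perturbations for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    pROC,
    pracma
Config/testthat/edition: 3
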