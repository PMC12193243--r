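Package: tripletrx
Title: Growth-Rate Metrics, Bliss Synergy, Transcriptomic Subtyping and
    Xenograft Efficacy Statistics for Multi-Drug Combination Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for triplet drug-combination studies
    in breast-cancer models: growth-rate (GR) inhibition metrics with GR50/IC50
    dose-response fits, Bliss-independence synergy scoring for 2- and 3-drug
    factorial surfaces, a bulk-transcriptome subtype workflow (count filtering,
    median-of-ratios normalization, variance-stabilizing transform, batch
    correction, variable-gene selection, k-means cluster-number diagnostics,
    PCA embedding and elastic-net shift projection of new samples into a frozen
    embedding), negative-binomial Wald differential expression with
    Benjamini-Hochberg correction, permutation-based preranked gene-set
    enrichment, delta-delta-Ct relative quantification, and xenograft efficacy
    statistics (caliper volumes, percent tumor growth inhibition, regression
    calls, ANCOVA). Seeded synthetic-data generators with known ground truth
    exercise every stage end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    cluster,
    glmnet,
    limma,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    DESeq2,
    SummarizedExperiment
Config/testthat/edition: 3
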