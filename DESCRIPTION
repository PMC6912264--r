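Package: proteoconsensus
Title: Consensus Differential Expression for Label-Free Proteomics with
    Left-Censored Multiple Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for label-free proteomics differential
    expression in a two-treatment by two-duration xenograft design.
    Zero intensities (non-detections) are handled along two routes: a
    missing-value dataset in which they are neglected, and five
    independently seeded imputations from a down-shifted normal
    distribution in the low-expression range (Perseus-style left-censored
    imputation, width 0.3 and down-shift 1.8 in per-sample standard
    deviation units). Per-protein one-way ANOVA with pooled-variance
    planned contrasts is run on each of the six datasets and proteins are
    called differentially expressed by a consensus rule (nominal p < 0.05
    and absolute linear fold change > 1.5 in the missing-value dataset or
    in more than three of the five imputed datasets). Downstream surfaces
    include hierarchical clustering with Pearson dissimilarity and
    complete linkage, volcano tables, and Fisher's exact gene-set
    enrichment with Benjamini-Hochberg adjustment. A synthetic-data
    generator emulates the xenograft intensity tables (two-species
    composition, planted effects, intensity-dependent left-censored
    missingness) so that every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
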