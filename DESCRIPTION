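Package: pascloud
Title: Pathway Activation Scoring and In Silico Geroprotector Screening
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores age-related disturbance of a "signaling pathway cloud"
    from young/old transcriptomes and ranks candidate geroprotective drugs
    by their ability to drive old expression profiles back toward the young
    state. Implements old-to-young expression ratios (OYR), tolerance-interval
    flags (BTIF), activator/repressor-weighted log-additive pathway activation
    strength (PAS), the multiplicative signal pathway cloud disturbance (SPCD)
    estimator, hypergeometric over-representation analysis with
    Benjamini-Hochberg correction for building the pathway cloud from a gene
    list, in-silico application of drug target fold-changes with
    disturbance-minimization ranking, and a seeded synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: GeneExpression, Pathways, GeneSetEnrichment, SystemsBiology,
    Transcriptomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
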