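Package: bprsig
Title: Bayesian Probit Regression Gene-Expression Signatures for Lung Disease
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Develops and validates binary diagnostic gene-expression
    signatures from whole-lung microarray profiles. Implements the full
    workflow: expression-matrix and phenotype I/O with cohort summary
    statistics, feature filtering and coefficient-of-variation selection,
    unsupervised structure analysis (Pearson-distance UPGMA clustering,
    PCA, lobe-pair intraclass correlation), empirical-Bayes moderated
    t differential expression with Benjamini-Hochberg FDR control, SVD
    metagene factors with Bayesian probit regression fitted by
    latent-variable Gibbs sampling, leave-one-out model-size selection by
    sum of deviances, cross-platform signature transfer through
    many-by-many feature mapping with scale/shift normalization, and
    ROC/Youden diagnostic evaluation. A seeded synthetic-cohort generator
    emulates the paired-lobe, biopsy/explant cohort structure so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
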