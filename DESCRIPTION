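Package: partprs
Title: Partitioned Polygenic Risk Scores for Liver Fat Genetics
Version: 0.1.0
Authors@R:
    person("partprs", "developers", email = "partprs@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates partitioned polygenic risk scores (pPRS)
    that split liver-fat-associated genetic variants into a "discordant"
    (liver triglyceride retention: raises liver fat, lowers circulating
    triglycerides) and a "concordant" (systemic: raises both) pathway.
    Provides per-variant association scans under multiple adiposity
    adjustments with rank-based inverse normal transforms, LD clumping and
    stepwise conditional selection of independent loci, pleiotropic locus
    merging, sign-concordance partitioning and weighted-sum scoring,
    logistic and Cox outcome models with Wald and AIC score comparisons,
    Bayesian non-negative matrix factorization soft clustering of
    variant-trait z-score matrices, causal mediation analysis with
    sensitivity to unobserved confounding, penalized predictor selection
    with nested cross-validation, inverse-variance fixed-effect
    meta-analysis, and a synthetic-cohort generator with a planted
    two-pathway architecture for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics
Config/testthat/edition: 3
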