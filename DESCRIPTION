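Package: fluenspace
Title: Semantic-Space Scoring of Category Fluency Transcripts
Version: 0.1.0
Authors@R:
    person("fluenspace", "maintainers", email = "maintainers@fluenspace.org",
           role = c("aut", "cre"))
Description: Item-level analysis of semantic (category) fluency performance.
    Builds a two-dimensional semantic map from word-embedding cosine
    distances (classical multidimensional scaling followed by t-SNE),
    assigns every produced item to exactly one semantic sub-category
    (k-means or a manual label map), scores per-participant movement
    metrics (words, sub-categories, switches, returns, word-count-adjusted
    variants, and visitation profiles), and compares diagnostic groups with
    one-way ANOVA, MANOVA (Wilks' lambda), Spearman correlations, and
    multinomial logistic models (likelihood-ratio tests, Nagelkerke pseudo
    R-squared, AIC/BIC, confusion matrices). A synthetic-data module
    generates clustered embedding spaces and group-structured fluency
    cohorts so the full pipeline is testable without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rtsne,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
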