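Package: jellynet
Title: Small RNA Profiling and miRNA Regulatory Network Analysis of Honey
    Bee Larval Jelly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for small-RNA sequencing of honey bee larval
    food (worker versus royal jelly): length filtering, exact-match
    annotation of collapsed sequence tags, category composition and digital
    miRNA expression; Audic-Claverie count tests and fold changes for
    two-library differential abundance; seed-match target prediction and an
    anti-correlation miRNA-mRNA regulatory network with MCODE-style module
    detection, Poisson-binomial co-targeting statistics, and hypergeometric
    term enrichment; LOWESS normalization, day-course paired tests and
    trend-shape classification; and feeding-experiment morphometrics
    (one-way ANOVA, Tukey HSD, and t-tests from raw data or published
    summary statistics). A synthetic-data generator with planted ground
    truth emulates the statistical structure of the study designs so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
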