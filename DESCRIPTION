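Package: famevo
Title: Comparative Gene Family Evolution of Fungal Proteases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of gene family evolution on dated
    species trees, built around fungal protease families. Implements a
    single-rate stochastic birth-death model of gene family size (filtering,
    pruning likelihood, rate estimation, Monte Carlo family p-values,
    ancestral counts and per-branch expansion/contraction calls),
    duplication-loss reconciliation of rooted gene trees with weighted event
    costs and bootstrap-threshold rearrangement, reverse conservation
    analysis of protein alignments (empirical-Bayes site rates, normalized
    sliding-window profiles, variable-region and functional-divergence
    calls), a random-effects-likelihood codon model scan for site-wise
    positive selection with Bayes factors, and RT-qPCR relative expression
    analysis via the 2^-ddCt method with ANOVA and Fisher LSD letter groups.
    Seeded synthetic-data generators make every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
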