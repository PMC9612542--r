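Package: crashrules
Title: Association Rule Mining and Rules-Graph Analysis of Multi-Fatality Crash Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for multivariate analysis of severe road-crash records using
    association rule mining and rules-graph structures. Crash tables are encoded as
    boolean transactions over a factor catalog; frequent itemsets and rules are mined
    with an Apriori level-wise search under support/confidence/lift thresholds;
    redundant rules are pruned by lift-increase (LIC) against base rules, screened by
    one-sided Fisher's exact tests with Bonferroni correction, and filtered by a
    declarative meaningfulness blacklist. Kept rules are cast into a directed graph of
    factor and rule nodes on which degree, closeness, PageRank and Louvain modularity
    identify key contributing factors and crash patterns. A synthetic transaction
    generator with planted rules of known support, confidence and lift makes every
    stage verifiable against closed-form expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
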