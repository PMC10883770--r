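Package: ratecov
Title: Evolutionary Rate Covariation on Reference-Constrained Gene Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects co-evolving gene pairs from the covariation of
    branch-specific evolutionary rates across gene phylogenies whose
    topologies are constrained to a reference species tree. Branch lengths
    are matched across trees by bipartition, normalized against the
    reference tree, filtered for outliers, Z-transformed and correlated
    (Pearson), with Bonferroni control over each comparison family.
    Includes quartet-congruence screening of reference genes, a candidate
    filter against a reference-gene set, hypergeometric pathway
    enrichment, network comparison statistics (edge Jaccard index and
    nominal assortativity, each with permutation nulls), and a synthetic
    data generator that plants rate covariation in simulated gene trees
    so the whole pipeline can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
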