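Package: lbdgraph
Title: Literature-Based Discovery over Entity Co-Occurrence Graphs
Version: 0.1.0
Authors@R:
    person("LBD", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Builds entity-level co-occurrence graphs from annotated
    biomedical text (PubTator pipe/TSV or an internal JSON-lines format),
    scores entity associations with eight co-occurrence metrics (count,
    document count, Jaccard, symmetric conditional probability, normalized
    pointwise mutual information, chi-squared, t-test and log-likelihood
    ratio), and answers open- and closed-discovery queries in the ABC model
    with configurable path aggregation and accumulation functions. Includes
    a deterministic synthetic-corpus generator with plantable indirect
    associations, table-driven identifier generalization, and a time-sliced
    evaluation harness (cutoff snapshots, A-C document exclusion, rank of
    the expected node, median-rank summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
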