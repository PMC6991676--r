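Package: stagenet
Title: Dynamic Differential Co-Expression and Network Analysis Across
    Ordered Disease Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies dynamic molecular signatures along an ordered
    multi-stage disease progression from bulk expression profiles.
    Implements transition-wise differential expression with
    Benjamini-Hochberg control and dynamic-DEG overlap, differential
    co-expression via per-stage Pearson correlations and the d-PCC link
    statistic, projection of dynamic links onto a merged background
    protein-protein interaction network with hub-degree ranking and
    shared-neighbour scoring, weighted co-expression module detection
    (soft-threshold scan, topological overlap, eigengenes, module-trait
    statistics, intramodular connectivity), and hypergeometric
    over-representation against GMT gene-set collections. A synthetic-data
    generator plants every structure the analysis assumes, so the whole
    pipeline is testable end to end without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    mclust,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
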