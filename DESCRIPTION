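Package: diffcoexpr
Title: Differential Co-Expression Network Analysis with Local Partial
    Correlation and Key-Driver Topology
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds condition-specific gene co-expression networks from
    multiple expression datasets by Fisher combined-probability
    meta-analysis with a cross-dataset direction-consistency filter,
    detects differentially correlated gene pairs (correlation gains and
    losses) between two biological states, infers local partial
    correlation (LPC) networks for settings where variables outnumber
    samples, and quantifies the topological position of differentially
    correlated genes relative to key-driver genes through minimum
    shortest paths and bipartite betweenness centrality. Includes
    causal-gene enrichment statistics, knockdown growth metrics, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: GeneExpression, Network, GraphAndNetwork, DifferentialExpression,
    NetworkInference
RoxygenNote: 7.3.3
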