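Package: metabodule
Title: Discovery of Disease-Associated Modules in Bipartite Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies custom, condition-associated metabolic modules by
    projecting per-feature association p-values (enzymes from metagenomics,
    metabolites from metabolomics) onto a global bipartite enzyme-metabolite
    network. Per-omic p-value distributions are modelled with a beta-uniform
    mixture to derive an FDR-based anchor threshold; an iterated Monte-Carlo
    labelling scheme estimates a co-membership matrix between anchor nodes;
    anchors are clustered by average linkage and each cluster is completed
    into a connected subgraph with a shortest-path Steiner-tree heuristic.
    Module significance is assessed with a topology-aware permutation test
    that shuffles p-values within node types, plus over-representation
    analysis utilities for comparison with predefined pathways. A synthetic
    data generator with planted modules supports benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
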