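Package: sennet
Title: miRNA and lncRNA Regulatory Network Analysis for Cellular
    Senescence Transcriptomics
Version: 1.0.0
Authors@R:
    person("sennet", "developers", email = "sennet@example.org",
           role = c("aut", "cre"))
Description: Builds and analyses integrated miRNA-lncRNA-mRNA bipartite
    regulatory networks from differential-expression tables and
    regulator-target interaction tables, as used in transcriptomic studies
    of cellular senescence. Provides Benjamini-Hochberg FDR selection with
    fold-change thresholds, merged bipartite network construction restricted
    to differentially expressed targets, degree-centrality hub ranking with
    top-k selection, co-regulation partition statistics, hypergeometric
    overrepresentation analysis over GMT gene-set collections, SPIA-style
    topology-based pathway impact analysis with bootstrap significance, and
    regulator overlay counts on pathway genes. A seeded synthetic-data
    module generates differential-expression tables, heavy-tailed
    interaction tables with planted hubs and controllable target-set
    overlap, and small signed pathway topologies, so the whole pipeline is
    testable without external downloads. Includes SIF/GraphML export for
    Cytoscape and a subcommand-style pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
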