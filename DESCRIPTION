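Package: pcgrn
Title: Multi-Layer Hierarchical Gene Regulatory Networks via First-Order
    Partial Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs multi-layer hierarchical gene regulatory networks
    from time-series expression data using a triple-gene, first-order
    partial-correlation algorithm: structural genes are screened for
    co-expressed pairs (Pearson CC with an exact t-test), and a transcription
    factor is declared a joint regulator of a pair when conditioning on it
    destroys the pair's co-expression (partial correlation below threshold).
    Layers are assembled bottom-up, giving a directed acyclic hierarchy of
    regulators over structural genes. Includes a planted-network simulator
    (linear regulation with replicate-level Gaussian noise over a time
    course) for benchmarking recovery, recovery scoring, counts-per-million
    low-expression filtering, readers and writers for the tabular formats
    involved (expression and count TSV, gene catalogs, GMT gene sets), and
    network export to edge-list TSV, SIF and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
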