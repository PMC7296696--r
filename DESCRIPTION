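Package: sscentrality
Title: Source/Sink Centrality for Directed Biological Pathway Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes Source, Sink, and combined Source/Sink (SSC) variants
    of spectral and distance-based graph centralities (degree, PageRank,
    Katz, Laplacian influence, harmonic closeness) on directed pathway
    graphs, together with a validation pipeline that relates topological
    importance to a-priori important gene sets: within-pathway quantile
    ranking, pooled quantile regression, cumulative-distribution (KS)
    comparison, per-pathway Welch and Wilcoxon tests with
    Benjamini-Hochberg FDR control, and a dampening-factor sensitivity
    scan. Reads KEGG KGML pathway files, edge-list TSV, and GMT gene
    sets, and ships a synthetic generator of layered pathway-like graphs
    with planted important genes so the whole pipeline runs without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
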