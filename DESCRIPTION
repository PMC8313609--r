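Package: psygset
Title: Gene-Set Similarity Profiling of Disease Clusters at Multiple
    Biological Levels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Top-down comparison of diseases through their curated
    gene-disease association (GDA) gene-sets. Diseases are compared via a
    Jaccard similarity matrix, grouped into global clusters by principal
    component analysis and into branches and subgroups by hierarchical
    clustering, then profiled at pathway, cell-type, drug-target and
    chromosome levels with hypergeometric overrepresentation analysis and
    Benjamini-Hochberg FDR control. Each level is summarised by a density
    index (the fill fraction of significant disease-by-annotation cells
    within a theme) and levels are ranked by how well clustering diseases on
    their enrichment profiles reproduces a reference partition, using the
    Rand index with a size-preserving permutation null. Includes a synthetic
    GDA generator with planted cluster structure, ubiquitous and
    cluster-private annotation themes, drug signatures and chromosome bias
    for ground-truth-bearing benchmarks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
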