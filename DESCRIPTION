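Package: pbin
Title: Structure Analysis of Phage-Bacteria Infection Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds binary phage-bacteria infection matrices (PBIMs) from raw
    spot-test lysis scores, clusters phage and host infection profiles by
    Jaccard distance with complete-linkage agglomeration, quantifies network
    nestedness (NODF) and bipartite modularity (Barber's Q, optimized by
    weighted label propagation with agglomerative refinement), ranks both
    statistics against fixed-fill, margin-weighted and margin-preserving
    (curveball) null models with one-tailed permutation tests, enumerates
    maximal bicliques of the bipartite infection network, and provides the
    supporting nonparametric statistics (Friedman, Dunn's post hoc, Mantel,
    Spearman). A synthetic-matrix generator reproduces the canonical
    one-to-one, modular, nested and random network structures, including a
    Salmonella-scale emulator with exact literature column margins, so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
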