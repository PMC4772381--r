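Package: elpa
Title: Overlapping Community Detection by Edge Label Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects link communities and node communities in undirected,
    unweighted networks by edge label propagation (ELPA): a degree-ordered
    greedy edge covering initializes candidate link communities, a
    triangle-rule label propagation condenses them, trend labels recover
    memberships a vertex has lost, node label propagation assigns vertices
    (possibly to several communities), and edges whose endpoints share no
    label are flagged as bridges. Includes cover-quality metrics (disjoint
    and overlapping normalized mutual information, Girvan-Newman and
    belonging-coefficient overlap modularity, partition density) and seeded
    planted-partition and LFR-style benchmark generators with ground-truth
    covers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
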