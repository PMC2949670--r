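Package: cfanet
Title: Protein Complex Prediction by k-Connected Subgraph Decomposition of
    Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein complexes from unweighted protein-protein
    interaction (PPI) networks by decomposing the network into maximal
    k-connected subgraphs for increasing k, filtering candidates by size,
    diameter and cluster score, and optionally segregating the network into
    localization groups derived from informative Gene Ontology cellular
    component terms before prediction.  Includes overlap-based evaluation of
    predicted clusters against reference complex catalogs (precision, recall,
    F-measure), co-localization and connectivity scores of complex sets,
    redundant-cluster removal, seeded synthetic benchmark generators with
    planted k-connected cores, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
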