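Package: lisindex
Title: Interactome-Pathway Mutual Enrichment and Lithium Sensitivity Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies mutual enrichment between the network neighborhoods
    (interactomes) of lithium-sensitive genes and disease-associated pathway
    gene sets. Extracts confidence-thresholded k-hop interactomes from a
    weighted protein-protein interaction network, computes hypergeometric
    over-representation p-values, calibrates them into empirical p-values
    against ensembles of size-matched random null gene sets, combines the
    per-disease block of empirical p-values by geometric mean into a
    lithium sensitivity index, ranks diseases, and scores key genes by their
    frequency at interactome-pathway cross sections. Ships a synthetic study
    generator with planted signal so the whole pipeline is testable offline,
    plus a staged command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
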