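Package: oncomodule
Title: Oral-Cancer-Associated Network Modules and Their miRNA Regulators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An integrative pipeline for identifying protein-protein
    interaction network modules associated with the malignant
    transformation of oral leukoplakia, and the microRNAs that regulate
    them. Differentially expressed genes and miRNAs are scored with
    two-sample t-tests; overlapping network modules are detected by
    k-clique percolation; each module's relevance is the mean member
    t-score, calibrated against a gene-resampling permutation null;
    topologically important genes (hubs by scaled connectivity, intra-
    and inter-module connectors by connecting score) are extracted; and
    miRNA regulators are called by Fisher enrichment of their targets in
    modules together with an expression-direction anti-correlation rule.
    A synthetic-data generator with planted modules and regulators makes
    every stage testable without external downloads, and transcribed
    reference tables allow the published summary figures to be
    recomputed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
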