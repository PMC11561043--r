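Package: cogmap
Title: Cognate Ligand Mapping and Domain-Ligand Interaction Graphs for
    Enzyme Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps ligands bound in enzyme structures to their cognate
    ligands by maximum-common-substructure (PARITY) similarity, classifies
    protein domain-ligand interaction modes from per-residue contact
    tables, profiles the chemical promiscuity and specialization of domain
    families, completes partial Enzyme Commission annotations of protein
    chains via cognate-ligand matching, and assembles the results into
    node/edge flat files suitable for bulk import into a graph database.
    Includes a synthetic-fixture generator with planted ground truth so
    every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    ChemmineR,
    Rcpp,
    cluster,
    dplyr,
    jsonlite,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
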