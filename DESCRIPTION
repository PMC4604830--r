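Package: phenosynth
Title: Ontology-Driven Synthesis of Presence/Absence Morphological Supermatrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds synthetic presence/absence character supermatrices from
    Entity-Quality (EQ) annotated morphological studies by reasoning over an
    anatomy ontology's subclass, partonomy, and developmental-precursor
    relations. Presence of a structure entails presence of the wholes,
    superclasses, and precursors it depends on; absence propagates in the dual
    direction. The package evaluates OWL-style class expressions to pick
    characters and taxa, assembles an entity-by-taxon matrix with full per-cell
    provenance (asserted versus inferred support), detects and classifies
    conflicting cells, finds isomorphic character clusters and classifies their
    ontological causes, computes missing-data and sampling reports, and reads
    and writes a restricted OBO dialect, a JSON study-bundle format, and NeXML.
    A seeded fixture generator produces random ontologies, taxonomies, and
    annotated study bundles with a ground-truth ledger for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
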