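Package: ontodiff
Title: Diff Computation and Change Classification for Versioned Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the difference between two versions of an OWL/RDF ontology
    as a partition of low-level triple changes into basic changes, matcher-dependent
    heuristic changes (merge, split, rename, attribute-value change) and
    deterministic complex changes (subgraphs, leaves, moves, obsolescence,
    individual reclassification). Detected changes are emitted as instances of a
    bundled change-action taxonomy and can be serialized to Turtle or JSON.
    Includes a pluggable matcher interface (built-in lexical matcher, TSV or
    Alignment-Format mapping ingestion), comparison metrics between tools and
    matchers, and a seeded synthetic-ontology generator that plants ground-truth
    labeled changes for every change action.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    stringi,
    readr,
    jsonlite,
    xml2,
    yaml,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
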