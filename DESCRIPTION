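Package: belminer
Title: Semi-Automated Extraction of Causal Biological Knowledge into BEL Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for semi-automated curation of causal biological knowledge
    from free text into the Biological Expression Language (BEL). Provides a
    parser, serializer and syntax validator for a BEL subset (BEL Script and
    XBEL formats), dictionary-based named-entity recognition and trigger-pattern
    regulation-event extraction, conversion of events into BEL statements with
    evidence and context annotations, programmatic curation edits with
    re-validation, compilation of BEL documents into a knowledge assembly model
    (KAM) multigraph with causal and non-causal edge semantics, XGMML export
    for Cytoscape, and analyses of network topology (degree, hubs, scale-free
    fit), network comparison, evidence overlap and curation-efficiency metrics.
    Deterministic generators for synthetic annotated corpora, BEL corpora and
    random graphs make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
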