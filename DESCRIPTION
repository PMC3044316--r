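Package: pathwaylint
Title: Rule-Based Validation and Complementation of Curated Biological
    Pathway Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality control for manually curated biological pathway
    models represented as bipartite entity/process graphs (the
    place/transition view used by Petri-net based pathway editors). Ships
    a registry of 40 event-condition-action rules that check structural
    correctness (one role per entity/process pair), biological-event
    semantics (cardinality, participant type, cellular location, feature
    type, stoichiometry, and cross-reference relationships for 36
    biological events in five groups), and complement a model with
    unknown-production, binding, and unknown-degradation processes so
    that every species has a source and a sink before dynamic simulation.
    Includes a documented JSON model dialect, GraphML export, a synthetic
    model generator with targeted violation injection, and command-line
    entry points.
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
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
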