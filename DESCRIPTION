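Package: nestsgg
Title: Scene Graph Generation for Insect Behavior at Nest Entrances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive recognition of bee and ant behavior at nest
    entrances through scene graph generation. Builds region graphs from
    captioned image regions, fuses them into scene graphs, predicts
    subject-predicate-object triplets by combining a class-prior branch, a
    paired-feature branch and a visual-context branch, refines node
    representations with a message-passing graph network, answers typed
    questions from the graph, and evaluates with a staged object
    recognition / bounding-box / scene-description protocol. Ships a
    deterministic synthetic nest-entrance scene generator with full ground
    truth that emulates the schema of field datasets (Visual-Genome-dialect
    region descriptions, synset-canonicalized objects, attributes,
    relationships and question-answer pairs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
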