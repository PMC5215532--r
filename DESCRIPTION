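Package: pritx
Title: Annotation of Polycistronic pri-miRNA Transcription Units and Their
    Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls long, possibly polycistronic primary-miRNA transcription
    units from strand-specific nascent (chromatin-associated) RNA coverage,
    classifies them as dynamically versus constitutively transcribed across an
    ordered differentiation series, assembles candidate promoter and enhancer
    elements by multi-mark epigenomic colocalization within a flanking window
    (active marks in expressing samples, repressive marks in silent ones),
    detects localized acetylation dips at DNase summits, scans elements and
    genomes for degenerate IUPAC and position-weight-matrix motifs gated by
    per-base conservation, and nominates candidate regulator transcription
    factors by intersecting ChIP binding evidence with differential
    expression. Ships a deterministic synthetic-scenario generator with a
    ground-truth manifest so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
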