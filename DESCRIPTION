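Package: tlr4net
Title: Multiscale Logical Model of TLR4-Driven Innate Immune Response to
    Sterile Injury
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A synchronous simulator for multi-valued logical networks with
    clamping (in-silico knockout), attractor detection and exact exhaustive
    basin-of-attraction enumeration, together with a two-scale model of the
    innate immune response to sterile ischemic injury: an intracellular
    TLR4 signaling network (MyD88-dependent and MyD88-independent/TRIF arms)
    coupled to a tissue-level macrophage recruitment model. Includes a seeded
    random-network generator for property testing, a JSON model dialect with
    bundled model files, and one-command reproduction of the model's
    steady-state, basin and knockout-panel tables against bundled reference
    values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
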