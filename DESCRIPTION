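Package: larvanet
Title: Transport Networks and Flow-Based Subpopulation Detection for
    Larval Dispersal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates planktonic larval transport with vertical behavior
    and habitat-constrained settlement, summarizes dispersal as a directed
    weighted transport network on a hexagonal geodesic grid, detects flow
    communities with a two-level map-equation optimizer at configurable
    Markov time, and characterizes the resulting subpopulations with the
    mixing parameter, coherence ratio, fortress ratio, a
    source/sink/permeable/impermeable classification, community
    connectivity matrices, and boundary persistence across solution
    ensembles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
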