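Package: oxiflight
Title: Phase Analysis of Pulse-Oximetry Records from Hypobaric Chamber Flights
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing peripheral oxygen saturation (SpO2) and heart
    rate records acquired during simulated hypobaric-chamber flights with a
    supplemental-oxygen mask disconnection challenge. Provides a plain-text
    flight-record dialect (CSV per subject plus a JSON sidecar), automatic
    detection of mask disconnection/reconnection events, decomposition of the
    desaturation curve into six phase parameters (disconnection time,
    desaturation delay, hypoxia delay, desaturation time, hypoxia time,
    recovery time), segment slope fitting, record validity checks, declarative
    cohort filters, group curves and heat maps on disconnection-aligned grids,
    descriptive summaries, a synthetic record generator with analytic ground
    truth, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
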