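Package: mirclubs
Title: MicroRNA Co-Targeting Networks and Assorted-Club Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds microRNA similarity networks from target-prediction
    tables using the meet/min (Simpson) set-overlap index, selects binary
    thresholds by sweeping graph properties (density, transitivity,
    centralization, assortativity, path metrics), detects densely
    interconnected groups of top-degree hubs ("assorted clubs"), partitions
    the network into spheres of influence, and characterizes clubs by
    consensus target sets, broadly-targeted gene hubs, hub-overlap tests and
    classic Fisher GO enrichment with Benjamini-Hochberg correction.
    Includes cross-database robustness comparisons, expression-matrix
    normalization and node-overlay scaling, and a seeded synthetic-data
    generator with planted clubs, hub genes and expression shifts so every
    pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    limma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
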