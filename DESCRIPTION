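Package: urbanlink
Title: Multi-Species Urban Habitat Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing habitat connectivity of rare species across
    urban landscapes. Converts continuous habitat-suitability surfaces to
    binary habitat and species-specific resistance surfaces (negative
    exponential transform with road-cost mosaicking), extracts viable habitat
    patches, builds Graphab-style least-cost-path patch networks with the
    Probability of Connectivity (PC) index and its per-patch dPC
    decomposition, maps circuit-theory current density with a peripheral-node
    injection scheme, delineates normalized least-cost corridors with
    pinch-point and barrier analyses, and computes the clumpiness and
    connectance class metrics. Includes a seeded synthetic-landscape
    generator (autocorrelated suitability, roads, urban cores, protected
    areas, habitat-biased occurrences) so the whole pipeline runs and is
    tested without sensitive occurrence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    mgcv,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
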