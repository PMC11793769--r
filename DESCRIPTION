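Package: esluc
Title: Scenario Land-Use Simulation, Ecosystem Services and an SDG Index on
    Raster Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis chain for ecosystem-service assessment
    under land-use change scenarios on gridded landscapes: seeded synthetic
    landscape generation (spatially autocorrelated terrain, climate, soil and
    driver fields with a Markov-consistent land-use time series), a simplified
    Markov + patch-growing cellular-automata land-use allocator with
    scenario weights and conversion constraints, four raster ecosystem-service
    models (Budyko-curve water yield, carbon storage, InVEST-style habitat
    quality with distance-decayed threats, RUSLE-factor soil retention),
    entropy-weight aggregation into a total ecosystem-service surface, global
    Moran's I and Getis-Ord Gi* hot/cold-spot classification, and an
    ecosystem-service-based Sustainable Development Goal index.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
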