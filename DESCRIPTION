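Package: wildroute
Title: Habitat Suitability and Trafficking-Route Network Modeling for
    Live-Animal Trade Interdiction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stepwise decision-support toolkit for mapping probable
    live-animal trafficking routes. Fits presence-only maximum-entropy
    species distribution models for prey species, ensembles them into a
    prey-richness layer, derives a rule-based 0-7 habitat suitability
    index (HSI) with human-modification and crop-cover masks, extracts
    core habitat as kernel-density isopleth polygons, and routes
    origin-to-destination scenarios over a multimodal (road plus sea)
    transportation graph with Dijkstra shortest paths, Yen k-shortest
    routes, isochrones, and bottleneck node analysis. Includes a
    synthetic-world generator with known ground truth so every stage is
    testable without external geodata downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
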