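Package: tripleland
Title: Multi-Objective Rural Land-Use Reallocation for Carbon, Production
    and Biodiversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A spatial pipeline for exploring trade-offs between carbon
    sequestration, agricultural/forestry production and biodiversity under
    rural land-use reallocation. Builds per-cell benefit maps for converting
    each grid cell to arable, pasture, plantation forest or semi-natural
    habitat; scans a discrete weight simplex with a weighted-sum
    scalarization; allocates land optimally per weighting, with or without a
    conversion budget; and analyses the resulting scenario ensemble via
    Pareto frontiers, strictly-better sets and per-cell conversion-frequency
    (robustness) maps. A seeded synthetic landscape generator emulates the
    statistical structure of national land-cover, yield, peat-soil and
    species-occurrence inputs so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
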