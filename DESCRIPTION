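Package: parkaccess
Title: Floating Catchment Area Accessibility with Supply Competition and
    Multimodal Travel
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-step floating catchment area (2SFCA) accessibility models
    for urban green space and similar amenities: classic 2SFCA, Gaussian-decay
    G2SFCA, a supply-competition variant that weights facility capacity by a
    quality score, and a multimodal composite that mixes per-mode accessibility
    fields by daily travel-mode shares. Includes travel-cost construction
    (Euclidean baseline, speed-model travel times with transit corridors),
    zone-level population-weighted aggregation, global and local Moran's I with
    LISA cluster classification, a seeded synthetic-city scenario generator,
    and CSV/GeoJSON readers and writers with a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
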