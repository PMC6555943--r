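Package: obesopoi
Title: Validation of Geocoding-Service Points of Interest for Obesogenic
    Built-Environment Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to assess obesogenic built environments from
    geocoding-service point-of-interest (POI) exports. Parses
    Google-Places-style JSON, Overpass-style JSON and GeoJSON point
    collections into a common record form, removes duplicate listings, maps
    source-native labels to environmental factors and six broader categories
    via a crosswalk, restricts POI sets to circular or quadratic search
    areas, classifies literature evidence per factor with an evidence-ratio
    rule, and validates database hits against ground-truth audit records
    (sensitivity and positive predictive value, overall and stratified by
    category, with category exclusion). A seeded synthetic-data generator
    emulates per-area ground truth, per-service detection and commission
    errors and positional jitter so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
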