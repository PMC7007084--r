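Package: catchfca
Title: Floating Catchment Area Accessibility Analysis for Emergency Health Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring potential spatial accessibility to emergency
    health services on a road network. Computes network travel times from
    population centroids to facilities, the enhanced two-step floating
    catchment area (E2SFCA) index with a stepped three-zone distance-decay
    scheme, min-max standardized accessibility scores, isochrone
    population-coverage tables, regional summary statistics, and before/after
    comparisons of facility-closure reform scenarios. Includes a seeded
    generator of synthetic study regions (grid road networks, urban-core
    population mixtures, core-concentrated facilities and closure-based
    reforms) so the full pipeline is testable without restricted census or
    commercial street data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
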