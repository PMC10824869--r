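Package: reefrubble
Title: Susceptibility of Coral Reefs to Rubble Accumulation from Bathymetric Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for mapping the susceptibility of coral reef slopes to
    rubble accumulation from gridded bathymetry. Extracts down-slope transect
    profiles by bilinear interpolation, flags points where loose coral rubble
    can collect using a moving-window decision tree over local relief,
    aggregates transect results into reef- and region-scale susceptibility
    metrics, runs one-at-a-time parameter sensitivity analyses, and models
    depth and aspect effects on potential rubble cover with a two-component
    beta-regression mixture fitted by expectation-maximisation. Includes
    synthetic-data generators for terrain profiles, small reef bathymetry
    grids and beta-mixture proportion data so the whole pipeline is testable
    without external rasters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
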