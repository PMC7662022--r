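Package: exposcape
Title: Geospatial Personal-Exposure Variables for Cohort Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts environmental geodata layers (points of interest,
    land-use polygons, street networks, rasters, administrative units) into
    per-address personal exposure variables: quartic kernel density surfaces,
    buffer and zonal statistics, land-use mix entropy, street connectivity,
    a six-component walkability index normalised to 0-100, kernel-smoothed
    neighbourhood aggregates that mitigate the modifiable areal unit problem
    (MAUP), and inverse-distance-weighted interpolation of station
    observations. All computation is in a projected metric coordinate
    system. A deterministic synthetic-city generator provides every input
    layer type so the full pipeline is reproducible without external data,
    and results are exported as tables keyed by address or administrative
    unit, suitable for linkage to individual-level cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
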