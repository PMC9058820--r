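Package: greenonbrown
Title: Threshold-Based Green-on-Brown Vegetation Detection with an
    18-Band Multispectral Sensor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for proximal green-on-brown vegetation sensing in
    precision agriculture. Implements vegetation indices (ENDVI, NDVI,
    EVI, PSND and user-defined custom indices) computed from an 18-band
    multispectral reading, soil-calibrated threshold detection with a
    periodic sense/compare/trigger loop, cone-footprint deployment
    geometry (radius of detection, maximum traverse speed, feasibility
    rules), a reproducible synthetic spectral-scene simulator based on
    linear mixing of soil and vegetation endmembers, and a canonical
    CSV log format with round-trip reading, writing and re-analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
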