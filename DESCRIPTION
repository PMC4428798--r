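Package: harbourcam
Title: Shore-Based Camera Photogrammetry and Detectability Modelling for Harbour Dolphin Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-camera photogrammetric positioning of surfacing dolphins
    using an artificial-horizon depression-angle geometry with tide correction
    and landmark bearing interpolation; GPS calibration scoring; field-of-view
    and detection range/bearing analysis; an AR-1 binomial generalised
    estimating equations (GEE) detectability model with hourly subsampling,
    sparse-level filtering, collinearity screening and Wald-test backward
    elimination; and a cost-effectiveness comparison of camera versus
    field-personnel monitoring. A synthetic harbour simulator generates all
    inputs so every pipeline stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    car,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
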