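Package: ecoclimex
Title: Mechanistic Ecoclimatic Suitability Modelling for Pest Risk Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A CLIMEX-style mechanistic species distribution model on a
    52-week annual timestep: trapezoidal temperature and soil-moisture
    growth responses, cold/heat/dry/wet stress accumulation, degree-day
    generation counts, and an Ecoclimatic Index (EI) on the 0-100 scale.
    Includes station-to-grid inverse-distance interpolation with a
    lapse-rate elevation adjustment, additive GCM anomaly ("delta")
    calibration of future climates, a synthetic monsoon-gradient climate
    generator for fully reproducible experiments, favourability
    classification and area summaries, limiting-factor attribution and
    provincial impact indices, current-versus-future comparison (EI
    change, range shifts), occurrence-record validation, and
    one-at-a-time parameter sensitivity analysis. Parameterized by
    default for the polyphagous shot-hole borer Euwallacea fornicatus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
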