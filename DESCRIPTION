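Package: smipp
Title: Phenology and Physiology Decomposition of Annual GPP Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decompose the trend and inter-annual variability of
    annual gross primary productivity (GPP) into contributions from growing
    season start, maximum daily GPP, and growing season end. Implements
    seasonal-curve smoothing (sixth-degree polynomial for 8-day composites,
    singular spectrum analysis for daily series), threshold-based phenology
    indicator extraction, the SMIPP anomaly regression with its three
    sensitivity coefficients, trend and consistency-weighted variability
    attribution, preseason and summer climate-sensitivity analysis, and a
    seeded synthetic-data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
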