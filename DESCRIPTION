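Package: aquacot
Title: Physiomechanical Modelling of the Energy Cost of Shallow-Water Walking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to estimate the metabolic cost of transport of upright
    walking in shallow water from anthropometrics and sagittal-plane gait
    kinematics. Body segments are modelled as conic frusta discretised into
    strips; strip-theory pressure drag and buoyancy-reduced vertical load
    yield per-stride mechanical work and a predicted cost of transport under
    an assumed muscle efficiency. Includes indirect-calorimetry processing of
    breath-by-breath gas exchange, quadratic response-surface modelling of
    cost over speed and immersion depth with extrema search and iso-cost
    intersections against reference swimming and dry-land curves, a
    validation battery (prediction ratios, leave-one-out cross-validation,
    bootstrap confidence intervals, sensitivity analysis), and a synthetic
    cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
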