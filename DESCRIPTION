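Package: soyco2
Title: Photosynthetic Down-Regulation Analysis for CO2 Growth-Chamber Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for growth-chamber studies of C3 photosynthetic
    down-regulation under elevated CO2 (400-1600 ppm), built around soybean
    defaults. Fits Farquhar-von Caemmerer-Berry (FvCB) A-Ci curves by
    exhaustive limb-partition least squares to estimate Vcmax, Jmax and Rd;
    quantifies stomatal morphometrics (density, shape index, area index) and
    the spatial pattern of stomata via Ripley's K / L-functions with Monte
    Carlo complete-spatial-randomness envelopes; fits quadratic and linear
    CO2 dose-response curves with vertex (optimum) estimation and one-/two-way
    ANOVA; summarises tissue carbon, nitrogen and non-structural
    carbohydrates; and generates complete seeded synthetic studies with known
    truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
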