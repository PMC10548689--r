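Package: tgedge
Title: Simulation and Edge-of-Failure Analysis of Calibrated Fluorogenic
    Thrombin Generation Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward simulation of fluorogenic thrombin generation (TG)
    plate data with controllable optical and kinetic artifacts (inner
    filter effect, substrate depletion, AFC bleed-through, antithrombin
    deficiency), together with the analysis stack used to read such
    plates back out: internal linear calibration, calibrator-based CAT
    correction in three software-style variants, alpha-2-macroglobulin
    subtraction, thrombin-generation parameter extraction, reference
    normalization, and severity scans that locate the edge of failure of
    each correction method against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    deSolve,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
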