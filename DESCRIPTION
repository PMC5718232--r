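Package: imrtqa
Title: Calculation-Based IMRT Quality Assurance from Machine Log Files
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A toolkit for calculation-based patient-specific quality
    assurance of step-and-shoot IMRT deliveries.  Reads treatment plans and
    time-sampled linac delivery logs in documented plain-text dialects,
    verifies log integrity and patient identity, compares delivered machine
    parameters (gantry, collimator, jaws, MU, per-leaf MLC positions)
    against the plan under clinical tolerances, reconstructs MU-weighted
    fluence maps at the isocenter from plan control points and from log
    samples, and differences them pixel-by-pixel with 2%/3% passing rates.
    Also compares dose distributions from two calculation sources with the
    2D gamma index (3%/3 mm), dose-difference histograms and line profiles,
    and derives cumulative dose-volume histogram indices for plan-vs-plan
    comparison.  A synthetic plan/log/phantom generator with parameterized
    delivery-error injection makes the entire pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
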