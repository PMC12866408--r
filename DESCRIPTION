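Package: petkin
Title: Kinetic Quantification and Test-Retest Reliability for Dynamic PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for dynamic small-animal PET studies with
    an image-derived input function: metabolite-corrected plasma-parent input
    construction (biexponential parent fraction, linear plasma-to-whole-blood
    ratio), reversible two-tissue-compartment model prediction and fitting,
    Logan graphical estimation of the total volume of distribution,
    standardized uptake values, scan-truncation time-stability analysis, a
    test-retest reliability battery (rTRV, aTRV, Bland-Altman limits of
    agreement, variance-component ICC by REML), and effect-size / power
    planning for two-group designs. A synthetic-data module simulates input
    functions, frame-averaged time-activity curves and multi-animal
    test-retest cohorts with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
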