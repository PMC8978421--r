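Package: rddframes
Title: Dual-Frame Versus Cell-Only Random-Digit-Dialing Survey Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the consequences of dropping the landline frame
    from a dual-frame (landline + cell) random-digit-dialing health survey.
    Provides a synthetic-population generator with realistic telephone
    equipment gradients, a fieldwork simulator with Kish within-household
    selection and AAPOR disposition coding, dual-frame and counterfactual
    single-frame design weights from selection-probability formulas, raking
    ratio calibration to population margins, representativeness diagnostics
    (standardized distances and R-indicators), and design-comparison
    estimation (weighted prevalences, design effects, relative differences,
    AAPOR response rate 3).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
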