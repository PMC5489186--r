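Package: iodocard
Title: Colorimetric Paper Test-Card Analysis for Urinary Iodine Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads and simulates wax-patterned paper test cards that measure
    urinary iodine via the iodide-catalysed Sandell-Kolthoff reaction with a
    ferroin indicator. Provides a synthetic card-image generator with a
    monotone blue-purple-red colour response, fiducial-based image
    registration, per-zone red-minus-blue scoring, per-card linear calibration
    against on-card 0/100/300 ug I/L internal standards, WHO three-way iodine
    categorization, validation statistics (confusion matrices, weighted
    Cohen's kappa, accuracy and precision with calibration-range exclusions,
    median-based population status), and the arsenic mass-budget, TCLP
    leachate and remediation arithmetic needed to assess card disposal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
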