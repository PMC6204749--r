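Package: uricolor
Title: Colorimetric Readout of Paper-Based Uric Acid Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital readout pipeline for paper-based colorimetric detection of
    urinary uric acid via Prussian-blue formation. Converts photographed or
    scanned reagent spots to CMY gray intensities, fits and inverts a
    saturating calibration curve with censoring at the saturation
    concentration, applies a linear temperature correction, classifies
    estimates against the clinically acceptable range, and analyses
    colour-formation kinetics (reaction-order selection and rate-constant
    estimation). Includes a fully deterministic synthetic-fixture generator
    for spot images, calibration standards, kinetics and temperature series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    png,
    jpeg,
    tiff,
    EBImage,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
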