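Package: grapevit
Title: Berry Cell Vitality, Canopy Architecture and Shallow Network Models for Grapevines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based quantification of living and dead mesocarp tissue in
    fluorescein-diacetate stained grape berry halves, gap-fraction analysis of
    upward-looking canopy photographs (canopy cover, crown cover, crown
    porosity, leaf area index, clumping index), Savitzky-Golay derivative
    preprocessing of near-infrared berry spectra, and one-hidden-layer
    feedforward regression networks trained with Levenberg-Marquardt or
    Bayesian regularization, together with the accuracy, prediction-bound
    outlier and ANOVA/Tukey diagnostics used to evaluate them. Seeded
    synthetic-data generators provide every input kind with known ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    multcomp,
    jsonlite,
    png,
    jpeg,
    tibble,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
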