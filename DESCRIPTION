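Package: slreg
Title: Single-Landmark Image-to-Patient Registration for Navigated
    Laparoscopic Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid image-to-patient registration for ultrasound-guided
    laparoscopic navigation. Implements the Single Landmark registration
    method (tool-orientation prior plus one anatomical landmark, with
    translation-only re-registration at intraoperatively sampled points),
    classical least-squares fiducial registration with fiducial registration
    error (FRE) reporting, pivot calibration of tracked pointers, the
    tracked-ultrasound click-to-world localization chain, a virtual phantom
    simulator reproducing a table-displacement accuracy protocol, and target
    registration error (TRE) summaries with one-way ANOVA and Welch tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
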