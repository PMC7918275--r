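Package: chronotap
Title: Rhythms in Smartphone Tappigraphy and Wrist Actigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for daily-living chronobiology from smartphone
    touchscreen logs (tappigraphy) and wrist-worn actigraphy. Extracts proxy
    measures of cognitive processing speed (tapping speed, unlocking speed,
    app-locating speed) and smartphone usage from timestamped event streams,
    converts wrist acceleration to activity counts and scores sleep with the
    Cole-Kripke algorithm, characterises diurnal and circaseptan rhythms with
    Lomb-Scargle periodograms and fixed-period cosinor fits, runs circular
    statistics (Watson-Williams test, circular correlation) on acrophases, and
    compares cognitive performance pooled in pre-bed, in-bed, and rise windows
    tethered to actigraphy-defined sleep. Includes a synthetic cohort
    generator with known ground truth so every stage is testable without
    access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
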