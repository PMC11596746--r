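Package: kinelisa
Title: Kinetic Image Analysis for Centrifugal Microfluidic ELISA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies TMB (3,3',5,5'-tetramethylbenzidine) color development
    in a lateral-strobe-illuminated centrifugal microfluidic ELISA from a
    timestamped image series. Extracts per-chamber mean color signals in RGB
    or CIELAB space, normalizes them as ratios from the substrate-injection
    value so that chamber-position-dependent illumination cancels, corrects
    single-frame strobe artifacts (more than 5 percent change per second),
    smooths traces with a trailing 30 s moving average, and builds
    time-resolved log-linear calibration curves with an R-squared trajectory,
    earliest reliable read time, and blank + 3 SD limit of detection. Includes
    a seeded synthetic assay-image generator with known ground truth and a
    command-line pipeline (simulate, extract, analyze, report).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
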