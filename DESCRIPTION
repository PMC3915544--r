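Package: applegrader
Title: Machine-Vision Color and Size Grading of Apples in Multiple Color Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a real-time apple grading pipeline
    built on multicolor-space analysis. Converts 8-bit RGB images to HSV,
    CIE XYZ under illuminant D65, chromatically adapts to D55 with the von
    Kries transform, and computes CIELAB; removes the dark conveyor background
    by multi-plane thresholding (HSV saturation, XYZ luminance Y, CIELAB a*);
    quantifies red and yellow surface regions; converts pixel extents to
    millimetres with a fixed pixel calibration; and grades each fruit into
    four color/size categories with per-group classification-rate reporting.
    Includes a seeded synthetic apple-scene generator emulating the per-class
    color statistics of the reference data so the whole pipeline is testable
    without a camera rig, and a command-line front end for grading image
    batches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
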