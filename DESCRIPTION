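Package: facemotion3d
Title: Three-Dimensional Dynamic Quantitative Analysis of Facial Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Marker-based optical motion-capture toolkit for quantitative
    facial kinematics. Provides a synthetic six-camera capture rig with
    calibration wands, rod phantoms and a parametric 21-landmark face;
    wand-based direct linear transform (DLT) camera calibration with a
    systemic-error gate; multi-view triangulation, marker labelling and
    tracking; helmet-based head-fixed and anatomical reference frames;
    per-landmark kinematic summaries (displacement, direction, velocity,
    acceleration); rod-phantom accuracy validation with one-sample t-tests;
    and test-retest reliability via one-way intraclass correlation
    coefficients with F-based confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
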