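Package: lasertrace
Title: Automatic Video Scoring of a Laser-Pointer Wrist Movement-Sense Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Frame-by-frame scoring of a clinical tracing task in which a
    hand-held laser dot follows the thin black center line of a zig-zag
    target printed on an A3 board. Detects the target corners and the laser
    dot in video frames, calibrates pixels to board millimetres with a
    four-corner homography, segments trials from the dot's dwell at the
    trace termini, and computes movement Acuity (percentage of trial time on
    the line) and Speed (mm/s). Includes the reliability statistics used to
    evaluate such tests (two-way intraclass correlation with confidence
    intervals, standard error of measurement from consecutive-trial
    differences, repeated-measures ANOVA, Spearman speed-accuracy
    correlation, paired and independent comparisons) and a seeded synthetic
    scene generator with analytic ground truth for validating every stage
    without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
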