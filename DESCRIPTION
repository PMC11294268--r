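Package: segvar
Title: Interobserver Variability Analysis for Ultrasound Tumour Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying interobserver variability in 2D binary
    lesion segmentations, built around intraoperative B-mode ultrasound of
    brain tumours. Implements overlap and contour agreement metrics
    (intersection-over-union, Sorensen-Dice, symmetric Hausdorff distance on
    boundary pixels), axis-aligned bounding-box relaxation of segmentations
    with containment scoring, a tumour-border pixel-dispersion substudy that
    classifies the modality of the intensity distribution in a perpendicular
    band around a contour (with a blurred-circle phantom for calibration), a
    synthetic cohort generator simulating annotator boundary disagreement on
    ultrasound-like textures, and aggregation utilities (mean, median,
    interquartile range, IQR-reduction percentages) that reproduce published
    per-image agreement tables shipped as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
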