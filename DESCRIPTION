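Package: scquant
Title: Quantitative 3D Morphometry of Synaptonemal Complex Tomography Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying annotated 3D point models of the
    synaptonemal complex (SC) derived from electron tomography. Reads
    model2point-style point files and a native JSON model format, applies
    pixel-size and section-thinning (z-scale) calibration, and computes
    per-filament morphometrics: transverse-filament (TF) lengths and
    element indents via polyline-region intersections, central-region and
    central-element widths from nearest-neighbor distances between
    intersection points, TF densities per micrometer and per square
    micrometer from projected bounding rectangles, side asymmetry, and
    nearest-neighbor pairing classes (parallel, opposite, single). Includes
    an orthogonal-regression plane fit and a two-plane (k-planes) layer
    test of the TF arrangement, a synthetic SC generator with full ground
    truth for validation, and a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
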