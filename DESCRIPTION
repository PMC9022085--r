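Package: kymovel
Title: Red Blood Cell Velocimetry from Laser Line-Scan (Kymograph) Images
Version: 0.1.0
Authors@R: person("Kymovel", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to measure apparent red blood cell (RBC) velocity from
    space-time line-scan (kymograph) images acquired with laser scanning
    microscopy. Implements three image-processing algorithms (streak-angle by
    shear alignment, line-scanning particle image velocimetry by per-line-pair
    cross-correlation, and two-dimensional Fourier spectral-slope estimation),
    the analytic pixelation error models that predict when each algorithm is
    accurate, a scanning-parameter feasibility planner for typical vessel
    types, and a synthetic line-scan generator with known ground-truth
    velocity, tube hematocrit, defocusing and noise for closed-loop
    validation. Reads and writes 16-bit grayscale TIFF images with JSON
    sidecars and provides a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
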