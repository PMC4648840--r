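Package: tendondic
Title: Three-Dimensional Digital Image Correlation Strain Analysis for Tendon Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Full-field strain measurement of soft tissue under uniaxial load by
    stereo digital image correlation (DIC). Provides a seeded synthetic rig that
    renders speckle-image sequences of a loaded tendon specimen with exact
    ground-truth displacement, strain, grip slip and force; facet-based subset
    tracking with zero-mean normalized cross-correlation search and
    inverse-compositional Gauss-Newton subpixel refinement; two-camera direct
    linear transform calibration and triangulation; surface strain tensors from
    local least-squares displacement gradients; and the analysis layer used in
    tendon tensile testing: virtual extensometers, grip-slip quantification,
    accuracy/scatter assessment, stress-strain modulus fitting and cumulative
    strain distributions on a millimetre grid.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
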