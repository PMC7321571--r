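Package: cartidvc
Title: Digital Volume Correlation and Strain Uncertainty for
    Cartilage-Bone Micro-CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Local-approach digital volume correlation (DVC) for pairs of
    three-dimensional grayscale volumes such as micro-CT scans of
    cartilage-bone plugs. Tracks cubic sub-volumes by FFT-accelerated
    zero-normalized cross-correlation with sub-voxel Gaussian peak
    refinement and a multipass predictor scheme, computes the small-strain
    tensor and von Mises equivalent strain on the measurement grid, and
    quantifies measurement uncertainty with zero-strain and
    synthetic-deformation protocols (MAER/SDER per tissue region per
    sub-volume size). Includes a synthetic cartilage-bone phantom
    generator with known ground truth, rigid registration by normalized
    mutual information, anisotropic-diffusion denoising, marker-controlled
    watershed labeling, flat-punch indentation metrics, and CSV/VTK/TIFF
    input-output.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
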