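Package: cleftrecon
Title: Single-Image 3D Intraoral Reconstruction for Cleft Palate Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-based reconstruction of cleft palate surfaces from a
    single photograph. Provides a PCA statistical shape model over
    template-corresponded triangle meshes, pinhole-camera similarity-pose
    estimation from sparse 2D-3D correspondences, alternating ("flip-flop")
    pose/shape fitting of the model to dense 2D landmarks, a Gaussian
    negative log-likelihood landmark regressor with per-landmark
    uncertainty, a synthetic palate generator and software rasterizer for
    producing annotated training images, a dense video-annotation pipeline
    with quality filtering, and scaling experiments with exponential
    learning-curve extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tools,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
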