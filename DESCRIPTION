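Package: boneseg
Title: Gradient-Based Semi-Automatic Bone Segmentation and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic, gradient-based segmentation of bone from
    volumetric MRI- and CT-like images: per-slice Canny edge detection with
    normalized hysteresis thresholds, seeded selection of bone-boundary edge
    components, slice-to-slice boundary propagation, and conversion of the
    tracked boundaries into 3D point clouds and closed triangulated surface
    meshes. Includes the full validation tool-chain used to characterise such
    segmentations: bone/cartilage contrast, slice-weighted Dice overlap,
    rigid iterative-closest-point registration, and radius-matched signed
    surface distances restricted to a perimeter-reduced cartilage-adjacent
    region, together with a synthetic patella-like phantom generator that
    provides paired MRI/CT renderings with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    pracma,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
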