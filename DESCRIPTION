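Package: ecapnet
Title: Deep-Learning Surrogates for Thrombosis-Risk Mapping on Left Atrial Appendage Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to learn and evaluate surrogate models that map left atrial
    appendage (LAA) surface geometry directly to per-vertex endothelial cell
    activation potential (ECAP) thrombosis-risk maps, bypassing computational
    fluid dynamics at inference time. Includes triangle-mesh input/output and
    differential-geometry primitives (normals, curvature, cotangent Laplacian),
    wall-shear-stress index computation (TAWSS, OSI, ECAP), heat-method
    geodesic distances with bull's-eye surface flattening, a truncated-PCA
    statistical shape model with a dense regression network, an image
    encoder-decoder over flattened maps with masked loss, a spline-kernel
    graph convolutional network operating natively on meshes, cross-validation
    and sequential-scaling evaluation protocols, and a synthetic LAA generator
    with a closed-form hemodynamic oracle for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    xml2,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
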