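Package: spherereg
Title: Joint Spherical Registration of Cortical Geometry and Function
    with Atlas Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learning-based diffeomorphic registration of cortical surface
    data on the sphere. Subjects are parameterized onto a latitude-longitude
    grid; an encoder-decoder network predicts one joint and two
    modality-specific stationary velocity fields whose exponentials align
    folding patterns and task-fMRI contrast maps simultaneously, while an
    unbiased multi-channel atlas is learned as part of the model. Training is
    semi-supervised: functional maps enter the loss but are never network
    inputs, so inference needs geometry only. Includes a forward simulator of
    the generative model (smooth deformation priors, two-stage additive
    Gaussian noise) for controlled recovery experiments, sin(theta) area
    distortion correction, evaluation metrics (correlation to group mean,
    signed-rank tests, negative-Jacobian statistics, deformation recovery
    error), readers for FreeSurfer morph-data/surface and GIFTI overlays, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    xml2,
    optparse,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
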