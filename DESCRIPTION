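Package: capreg
Title: Video-Based Co-Registration of Scalp-Mounted fNIRS/EEG Probes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automatic spatial co-registration of cap-mounted fNIRS/EEG
    probes from consumer video. Detects solid-color fiducial stickers in
    frames and in a colored structure-from-motion point cloud, assigns the
    nine fiducial labels by RANSAC against a pre-registered model cap,
    fits a rotation + anisotropic-scale head transform into MNI space,
    interpolates channel positions with sum-to-one barycentric weights,
    and quantifies cross-session and cross-method agreement. Includes a
    synthetic-scene generator (ellipsoidal head, sticker clusters,
    Perlin-patterned cap, rendered frames) so the whole pipeline is
    testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
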