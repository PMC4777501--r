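Package: oipf
Title: Orbital Implant Positioning Frame Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the rigid-body deviation between a planned and an
    achieved orbital implant position. An implant-intrinsic reference frame
    (origin and aircraft-style roll/pitch/yaw axes defined on the implant)
    is established on a reference model; planned and achieved implant
    surfaces are chained through the frame with iterative closest point
    registration, and the residual transform is decomposed into roll, pitch
    and yaw angles (ZYX order), origin translations and key-point
    displacements. Includes STL mesh input/output, surface sampling,
    closed-form (Kabsch) and trimmed ICP rigid registration, Hounsfield
    threshold segmentation of post-operative CT volumes with connected
    component filtering and surface extraction, and a synthetic surrogate
    implant and CT phantom generator with known ground-truth poses for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
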