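Package: spinocurve
Title: Segmentation and Curvature Analysis of Cervical Flexion-Extension
    Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiautomatic analysis of lateral cervical spine radiographs
    taken in flexion, neutral and extension. Images are partitioned into
    intensity clusters by K-means, the cluster containing the vertebrae is
    cleaned by morphological erosion of its complement and two-pass
    connected-component labeling, and the spinolaminar line is recovered as
    the set of cluster boundary points lying within a proximity threshold of
    the reference background region. A sixth-order polynomial fit yields
    local curvature, average curvature, total rotation and, with a supplied
    bending-moment profile, flexural rigidity. Mirroring the image lets the
    same pipeline extract the contour of an implanted anterior cervical
    plate, whose lordotic radius is measured from an osculating circle at
    the plate mid-point. A phantom generator produces radiograph-like test
    images with exactly known geometry so every stage is verifiable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
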