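Package: lumenreg
Title: Structure-Feature 2D/3D Registration for Branched Luminal Organs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rigid 2D/3D registration of endoscopic images to a preoperative
    surface model of a branched luminal organ (e.g. the renal collecting
    system). Salient structural points are extracted from the cavity mesh by
    tangent-plane intersection and visibility tests, projected under candidate
    camera poses into "generated contours", and matched against "actual
    contours" extracted from 2D images by superpixel contrast analysis. The
    6-DOF pose is recovered by a coarse-to-fine differential-evolution search
    over a joint-probability mutual-information contour similarity with
    gradient and multi-view terms. Includes a synthetic branched-cavity scene
    generator and a software virtual-endoscopy renderer so the full pipeline
    is testable without clinical data, plus target-registration-error
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    rlang,
    jsonlite,
    yaml,
    png,
    tibble,
    ggplot2,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
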