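Package: mpsjc
Title: Geometric Instantaneous-Centre Model of the Metatarso-Phalangeal-Sesamoid Joint
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating instantaneous centres of rotation (ICR) of the
    metatarso-phalangeal-sesamoid joint complex from sagittal-plane articular
    geometry. Builds composite circular/elliptical-arc head profiles with
    sesamoid grooves, resolves rigid tangential contact against the fixed
    sesamoid-phalanx platform, intersects inward contact normals to obtain
    per-plane centres of rotation and a three-dimensional least-squares shared
    centre, sweeps the metatarsal declination angle to classify proximal and
    distal centre-of-rotation shifts, encodes variant morphologies with
    machine-checkable displacement predictions, and generates synthetic 0.5-mm
    section stacks with landmark recovery for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
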