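Package: glandseg
Title: Cross-Organ Gland Segmentation for H&E Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gland instance segmentation for hematoxylin-and-eosin stained
    tissue tiles via two parallel routes: direct gland segmentation, and
    stroma segmentation with gland recovery by inversion. Provides
    structure-preserving stain normalization by sparse non-negative stain
    separation in optical-density space, derivation of gland/contour and
    stroma/stroma-contour supervision masks from instance annotations, a
    dual-decoder Dense-U-Net implemented with an in-package compute engine,
    contour-fusion post-processing with dense-CRF refinement, Dice and
    Hausdorff evaluation, and a seeded synthetic H&E tissue generator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
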