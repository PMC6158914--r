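Package: cupseg
Title: Optic Cup Segmentation in Fundus Images by Vessel Inpainting and
    Local Chan-Vese Level Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automatic segmentation of the optic cup in digital fundus
    photographs. The green channel is contrast-enhanced with top-hat and
    bottom-hat morphological transforms, blood vessels are extracted by
    median-filter differencing and removed by a
    Bertalmio-Sapiro-Caselles-Ballester (BSCB) partial-differential-equation
    inpainting scheme that transports neighborhood-mean smoothness
    information along isophotes, and the cup boundary is recovered with a
    local Chan-Vese level-set model seeded at the centroid of the bright cup
    region. Includes pixel- and boundary-based evaluation metrics (F-score,
    radial boundary distance, vertical cup-to-disc ratio), a deterministic
    synthetic fundus-phantom generator with known ground truth, and an
    end-to-end pipeline with ablation and parameter-sweep harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    grDevices,
    stats
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
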