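Package: camseg
Title: Weakly-Supervised Tissue Segmentation from Image-Level Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns pixel-level tissue segmentation of histopathology image
    patches from image-level (multi-hot) class labels. A classification branch
    with a discriminative-activation layer produces category-specific
    activation maps; confident foreground/background regions obtained by
    thresholding are fused with dense conditional-random-field refinements
    into pixel pseudo-labels; a segmentation branch is trained jointly with a
    masked cross-entropy loss on confident pixels plus a Gaussian dense
    pairwise energy loss. Includes a seeded synthetic toy-histology data
    generator, mean-IoU evaluation with background exclusion, and mask/label
    file round-trips.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
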