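Package: virtualstain
Title: Virtual H&E Staining of Unstained Tissue Images by Dual
    Contrastive Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A three-stage pipeline that translates brightfield images of
    unstained tissue sections into virtually H&E-stained images.  Stage one
    segments tissue foreground by adaptive thresholding, registers the
    unstained image onto the stained frame with keypoint matching and a
    RANSAC-estimated homography, and cuts overlapping patches.  Stage two
    trains a dual contrastive learning GAN: two generators, two patch
    discriminators and two projection heads optimised with adversarial,
    identity and multilayer patchwise noise-contrastive (PatchNCE) losses.
    Stage three translates whole slides tile by tile and alpha-blends the
    overlapping tiles with a partition-of-unity weight matrix.  Includes
    Frechet distance (FID) and kernel (KID) evaluation metrics with a
    pluggable feature extractor, and a seeded synthetic paired-tissue
    generator so the full pipeline can be exercised and tested at desk
    scale without slide scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    stats,
    utils,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
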