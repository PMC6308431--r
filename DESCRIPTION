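Package: blastograde
Title: Automated Segmentation and Quality Grading of Bovine Blastocyst Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis pipeline for grading bovine blastocyst brightfield
    images on the IETS three-grade quality scale. Standardizes raw captures to a
    canonical 640x480 8-bit working image, locates the embryo circumference by a
    two-stage circular Hough transform on the thresholded gradient magnitude,
    isolates the expanded region (zona pellucida included), the reduced region
    (inner cell mass and blastocoel) and the trophectoderm annulus, extracts 36
    grey-level co-occurrence and shape variables pruned to 24 by iterated
    variance-inflation-factor elimination, and grades with a three-network
    feedforward ensemble whose architectures are found by a genetic algorithm.
    Includes a scaling algorithm that rescues small smartphone-through-ocular
    captures by variable-range Hough or watershed localization, cropping and
    bicubic expansion, plus a ground-truthed synthetic blastocyst image
    generator and the frequency statistics used to compare segmentation
    outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jpeg,
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
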