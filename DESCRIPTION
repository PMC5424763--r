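Package: seedvision
Title: Machine-Vision Grading of Seed Quality from Shape, Color and
    Texture Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A machine-vision pipeline for sorting seeds into good and
    reject ("NG") grades from color images of seeds on a dark background.
    Frames are segmented into per-seed regions by thresholding,
    morphological cleaning and hole filling; each region yields 15 shape
    descriptors (circularity, compactness, circumcircle defect ratio,
    elongation, eccentricity, ellipticity, roundness deviation, convex-hull
    angles and defect depth, symmetry area ratios), 6 color descriptors
    (RGB and HSI channel means), and 6 texture descriptors (gray-level
    co-occurrence matrix statistics over four orientations, plus a
    rotation-invariant local-similarity average and Tamura coarseness).
    Two three-layer sigmoid back-propagation networks (one on shape, one on
    color-texture features), sized by nh = ceil((ni + no)/2) and trained by
    online gradient descent to a mean-squared-error tolerance, are combined
    by an AND rule; inputs to each net are chosen by sequential floating
    forward selection against validation accuracy. A synthetic seed-image
    generator with controllable shape class, surface color and defect
    density provides labeled ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
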