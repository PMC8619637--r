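Package: endorecon
Title: Feature-Based Stereo Endoscope Surface Reconstruction and Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for feature-based three-dimensional reconstruction and
    motion tracking of soft-tissue surfaces filmed with a rectified parallel
    binocular endoscope. Provides FAST corner detection, a small
    convolutional patch-classification network used for descriptor-free
    stereo feature matching via per-category match matrices, disparity-based
    3D point recovery, a from-scratch incremental (Bowyer-Watson) Delaunay
    triangulator with Lawson local optimization, plane-projection
    triangulation of 3D point clouds, textured mesh assembly with OBJ/PLY
    export, class-based 3D feature tracking with blank handling and gap
    filling, and a seeded synthetic generator of rectified stereo sequences
    of a periodically deforming blob-textured surface with full ground truth
    for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
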