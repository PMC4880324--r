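Package: dmffd
Title: Direct-Manipulation Free-Form Deformation for 3D Segmentation Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interactive-style correction of 3D image segmentations by
    free-form deformation (FFD) of the segmentation surface on a trivariate
    Bernstein control lattice. A single 2D contour drag on an image slice is
    lifted to a 3D vertex constraint and turned into a smooth global or local
    shape correction by solving the inverse ("direct manipulation") FFD in the
    minimum-norm least-squares sense. Includes plane-mesh contour extraction,
    mesh rasterization, Dice and Hausdorff evaluation, synthetic ellipsoid
    fixtures with perturbed initial segmentations, a deterministic scripted-user
    simulator that emulates a slice-wise correction protocol, and replayable
    JSON interaction traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
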