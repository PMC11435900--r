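Package: l3seg
Title: Lightweight Skeletal Muscle Segmentation in Axial L3 CT Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: CPU-only, rule-based segmentation of skeletal muscles (the
    anterolateral abdominal wall band and the paraspinal groups) in a single
    axial CT slice at the level of the third lumbar vertebra (L3).  The
    pipeline combines Hounsfield-unit thresholding, Chebyshev distance-map
    isocontour selection, convex-hull band extraction, adaptive double
    thresholding from a Gaussian fit to the histogram peak, vertebra-anchored
    bounding boxes, and adaptive corner carving.  Includes boundary-based
    evaluation metrics (Dice, precision, recall, HD95, average surface
    distance), majority-vote consensus of multiple annotations, a synthetic
    L3 phantom generator with ground-truth label maps, and readers/writers
    for single-slice DICOM, NIfTI-1 and PNG masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    png,
    RNifti,
    stats,
    grDevices,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
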