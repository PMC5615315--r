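Package: tibiaslope
Title: Automated Slice-Wise Measurement of Tibial Slopes from Knee MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures medial, lateral, and coronal tibial slopes slice by
    slice from 3D knee MRI of the proximal tibia. Constructs a transverse
    plane through the tibial tuberosity, sagittal and coronal reference
    slices and axes from chord midpoints, locates plateau rim nodes by
    curvature analysis of sub-voxel bone contours, and reports signed
    per-slice slope profiles, articular concavity zones, and subject and
    cohort summaries. Includes a synthetic proximal-tibia phantom generator
    with analytic ground truth for validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
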