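Package: scleratopo
Title: Posterior Scleral Topography and Staphyloma Shape Parameters from
    Eyeball Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies posterior eyeball shape from binary eyeball
    segmentation masks (NIfTI or NRRD) or surface point clouds. Establishes
    the pupillary-foveal coordinate frame via a maximally inscribed sphere,
    places the hypothetical pre-elongation eye centre 12 mm posterior to the
    corneal vertex, and over the 120-degree posterior region computes the
    per-point distance to that centre (D) and the local sphere-fit curvature
    (C, 3 mm neighbourhoods). Renders topography maps and derives the seven
    staphyloma shape parameters (D_mean, C_mean, D_max, C_max, D_var,
    CD_mean, CD_max; percentile-based maxima), together with ROC area and
    normalized partial area over the high-specificity range used to evaluate
    them. Includes a synthetic phantom generator (ellipsoids with optional
    Gaussian angular protrusions, Type 0/1/2 morphologies) with analytic
    ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
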