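Package: bmmap
Title: Voxel-Wise Mapping and Outcome Analysis of Brain Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for voxel-wise analysis of brain metastasis topography on a
    common template grid: connected-component lesion labeling, centroid-based
    localization against a region atlas, tumor-frequency heatmaps, per-voxel
    two-sided Fisher exact-test maps (analysis of differential involvement,
    ADIFFI) with significant-cluster extraction, volume-normalized relative
    metastatic risk per region, and Kaplan-Meier/Cox survival analysis of
    lesion topography. Includes a synthetic-cohort generator (toy atlas,
    spherical lesions, covariates, survival times) so the full pipeline is
    testable without patient data, and an end-to-end pipeline runner with a
    reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    survival,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
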