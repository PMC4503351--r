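Package: mmmprofiler
Title: Multi-Dimensional Microscopic Molecular Profiling of Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for cyclic multiplexed tissue imaging: tile stitching with
    consensus overlap selection, DAPI-fiducial rigid registration across staining
    cycles, per-pixel multi-channel matrix extraction, unsupervised pixel
    profiling (PCA, k-means, nonmetric-MDS similarity colour coding, imputation
    fidelity), checkerboard-cross-validated linear discriminant classification of
    annotated histological features, and DAPI nuclei segmentation with a
    smaller-set overlap statistic. Includes a synthetic tissue phantom generator
    with full ground truth so every stage is testable without microscope data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
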