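Package: transectopt
Title: Sampling-Error Analysis and Design Optimization for Transect-Based Vegetation Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify plot-scale sampling error of the core
    transect-based vegetation monitoring methods (line-point intercept,
    canopy gap intercept, and vegetation height) and to choose
    minimum-effort sample designs. Computes the standard indicators
    (total foliar cover, species count, canopy gap size-class cover,
    mean vegetation height), subsamples full plot datasets into reduced
    designs (fewer, shorter, or more sparsely measured transects),
    fits nested Bland-Altman limits of agreement with MOVER confidence
    bounds to the full-minus-subsample differences across repeatedly
    sampled plots, and selects the lowest-effort designs meeting
    acceptable-difference criteria. Includes a spatial simulator of
    clustered plant canopies on 1-ha radial-transect plots so the whole
    pipeline can be exercised without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
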