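Package: mzadapt
Title: Resolution-Adaptive m/z Binning and Multi-Batch Integration for Orbitrap MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for turning centroided full-scan Orbitrap mass spectra into
    reproducible feature matrices. Fits the power-law dependence of resolving
    power on m/z, derives per-feature adaptive bucket widths from the fitted
    curve, fuses overlapping buckets, and integrates bucket sets across batches
    and platforms into a single observations-by-features table. Includes
    constant-Dalton and dynamic-ppm competitor binning, a ground-truth recovery
    benchmark (recovered/aggregated/clipped/missed taxonomy), binary
    classification metrics (F1, MCC, recall, precision), a synthetic
    multi-batch scan generator with known ground truth, mzML and CSV I/O, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr
Suggests:
    glmnet,
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
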