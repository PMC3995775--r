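Package: glenoidvault
Title: Landmark-Based Measurement of Glenoid Vault and Conventional Glenoid Version
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing glenoid version from named 3D scapular
    landmarks in scanner coordinates. Reconstructs the scapular plane and
    the three-dimensionally corrected slice, measures signed glenoid
    version (retroversion positive) with both the conventional (Friedman)
    scapular-axis method and the glenoid vault method, and supports Walch
    B2 intermediate glenoid lines. Includes intraclass correlation
    reliability analysis (one-way ICC(1,1) and two-way absolute-agreement
    ICC(2,1) with F-based confidence intervals), paired Wilcoxon and
    variance-ratio cohort comparisons, and a synthetic scapula generator
    with known ground-truth version for validation and power studies.
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
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
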