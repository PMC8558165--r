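Package: carepatterns
Title: Phase-of-Care Attribution of Cancer-Related Health Care Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cancer-related patterns of care from cancer-registry
    cohorts linked to administrative health databases using the direct
    (attribution) method: cross-sectional phase-of-care assignment on a
    prevalence date (initial, continuing, final), attribution of hospital,
    outpatient and pharmacy events through clinician-drawn code lists
    (D-lists), phase-stratified frequency tables and phase-weighted category
    distributions, and empirical validation of the code lists by a
    self-control (pre/post diagnosis) design with Welch-Satterthwaite
    two-sample tests and occurrence-weighted list concordance. Includes a
    seeded generator of synthetic linked registry and claims data with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
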