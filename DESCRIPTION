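Package: p300select
Title: Individualized Electrode Subset Selection for P300 Brain-Computer
    Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Offline analysis tools for P300-design brain-computer
    interface (BCI) calibration sessions. Provides stimulus-locked epoch
    containers with session-bundle input/output, common average
    referencing and ERP averaging, decimated feature extraction, stepwise
    linear discriminant analysis (SWLDA) calibration with split-half
    estimation of calibration accuracy, greedy forward electrode
    selection with an exhaustive-search oracle and leave-one-trial-out
    consensus scoring, flash-count tie-breaking between electrode
    subsets, exact one-sided binomial tests of per-subject improvement,
    and a seeded multi-channel ERP session simulator with typical and
    spatially atypical subject profiles.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
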