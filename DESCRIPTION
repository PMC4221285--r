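Package: avirange
Title: Presence-Only Species Distribution Modelling and Climate Versus
    Land-Use Attribution of Range Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling breeding-bird distributions from
    presence-only occurrence records with an L1-regularized
    maximum-entropy (maxent) model, and for attributing contemporary and
    projected range to climate versus land-use/land-cover (LULC)
    covariates.  Includes occurrence filtering (observation protocol,
    breeding-season window, 20-km spatial thinning), focal-window LULC
    covariates and topographic derivatives, buffered study extents with
    background sampling, ROC/AUC evaluation with
    maximum-sensitivity-plus-specificity thresholding, and a twelve-run
    simulation design that isolates climate-only and LULC-only change
    under emissions scenarios.  A synthetic-world generator provides
    landscapes, climate gradients, scenario transitions and virtual
    species with known suitability so that every stage can be validated
    against ground truth.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
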