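Package: ursadens
Title: Bear Density Estimation by Spatial Capture-Recapture and
    Resource-Selection Extrapolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating bear density from non-invasive genetic
    sampling at bait-free rub objects. Implements full-likelihood spatially
    explicit capture-recapture (SECR) with a hazard half-normal detection
    function, covariate models on the detection hazard, spatial scale and
    density, small-sample AICc model selection in two steps, density-surface
    prediction and region abundance by discrete summation. Also implements
    used-available resource-selection functions (RSF), habitat-bin abundance
    extrapolation from a reference area, and k-fold Spearman
    cross-validation. A synthetic-data module simulates landscapes, detector
    arrays and capture histories with known parameters for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
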