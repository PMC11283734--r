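Package: liversim
Title: Discrete Event Simulation of a National Liver Transplant Waiting List
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete event simulation of a small national liver transplant
    waiting list (modelled on Norway), built to quantify the spillover effects
    of expanding transplant eligibility to patients with nonresectable
    colorectal liver-only metastases (CRLM). Patients and donor grafts arrive
    as Poisson streams, are matched within AB0 blood groups with priority for
    acute liver failure and retransplant listings, and accrue life-years from
    parametric posttransplant survival distributions with a switch to
    life-table background mortality after ten years. The package includes the
    parametric survival machinery (five families, censored maximum likelihood,
    AIC/BIC selection), synthetic cohort generation, calibration utilities for
    under-specified inputs, replication management with burn-in and common
    random numbers, and break-even analysis of life-years gained and lost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
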