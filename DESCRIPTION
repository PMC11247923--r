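Package: stk11vep
Title: Assessment of Variant Effect Predictors Against an STK11 Kinase
    Activity Assay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking computational variant effect predictors
    against a cell-based luciferase reporter assay of STK11 (LKB1) kinase
    activity. Normalizes replicate-level luminescence to relative-wildtype
    (R-WT) activity, labels variants loss-of-function or wildtype-like,
    evaluates predictors with Pearson correlation, Kendall's tau and
    Mann-Whitney AUC under paired bootstrap resampling, ranks predictors,
    compares them with an Experimental-Max replicate-resampling performance
    ceiling, profiles per-variant prediction difficulty, and classifies
    variants clinically with a point-based ACMG/AMP evidence engine (PS3/BS3,
    PM2/BS1, PP3/BP4, PM5). Includes a synthetic-data generator emulating the
    nested biological/technical replicate structure of the assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
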