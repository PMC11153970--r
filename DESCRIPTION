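Package: adhclean
Title: Cleaning and Enrichment of Electronic Monitor Medication Adherence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cleans raw electronic-monitor (EM) medication adherence data and
    computes the daily binary implementation statistic at the monitor and
    patient level. Reads EM opening event exports and an investigator-curated
    Auxiliary Data workbook (monitoring windows, continuous and cyclic dosing
    regimens, pocket-dose and extra-opening corrections, nonmonitored
    periods, covariables), validates them against a strict sheet/column
    contract with a critical-error versus warning taxonomy, and writes a
    four-sheet implementation workbook plus error and warning logs. Includes
    a ground-truthed synthetic data generator for end-to-end verification and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
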