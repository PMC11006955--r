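Package: fpfundflow
Title: Family Planning Fund-Flow, Costing and Contraceptive Projection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for national family-planning (FP) financing analysis:
    projects women of reproductive age and method-specific modern contraceptive
    prevalence to a target year from a series of survey rounds, converts users
    by method into annual commodity quantities and sector spending via
    couple-years-of-protection (CYP) factors, assembles an institution-by-stage
    fund-flow matrix from a budget ledger with column shares, conservation
    checks and headline financing indicators, and exports SankeyMATIC flow
    text. Ships an Indonesia-2019 fixture encoding the published fund-flow
    tables and a synthetic-scenario generator with known ground truth for
    end-to-end testing.
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
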