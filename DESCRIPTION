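Package: finprot
Title: Financial Protection Metrics from Household Health Expenditure Surveys
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measures financial protection in health from household survey
    data: incidence and intensity of catastrophic out-of-pocket (OOP) health
    payments (head count, overshoot, mean positive overshoot) with
    distribution-sensitive rank-weighted variants built on concentration
    indices over weighted fractional expenditure ranks, and the
    impoverishing effect of OOP payments (poverty head count and poverty
    gap, gross versus net of health payments). Includes quintile-level
    descriptives of utilization and OOP spending, a seeded synthetic
    household-survey generator emulating the structure of the Mongolian
    Household Socio-Economic Survey 2012, and paper-style table rendering.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
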