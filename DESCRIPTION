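Package: cetuxcea
Title: Cost-Effectiveness of RAS-Guided Cetuximab for Metastatic Colorectal
    Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitioned-survival cohort model comparing first-line FOLFIRI
    chemotherapy with RAS-screened cetuximab plus FOLFIRI for metastatic
    colorectal cancer from a payer perspective. Weibull survival curves drive
    a three-state (progression-free, progressed, dead) trace over a ten-year
    horizon in 14-day cycles; costing covers chemotherapy, cetuximab dosing
    with vial wastage and a pay/donate patient-assistance calendar,
    RAS-screening loading, salvage therapy and terminal care. Outputs are
    discounted costs, life-years, QALYs, incremental cost-effectiveness
    ratios and net monetary benefit, with tornado-style one-way sensitivity
    analysis, probabilistic sensitivity analysis and cost-effectiveness
    acceptability curves. A synthetic Kaplan-Meier generator and Weibull
    fitting stage allow parameter-recovery testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
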