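Package: afscreen
Title: Health-Economic Evaluation of Population Screening for Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic model of one-time population screening for
    non-valvular atrial fibrillation (AF) followed by oral anticoagulation,
    set in Nigeria. A screening decision tree feeds a lifetime Markov cohort
    model run in 6-month cycles over AF, stroke, bleeding and death states;
    outputs are discounted costs, QALYs, incremental cost-effectiveness
    ratios and net monetary benefit. Includes probabilistic sensitivity
    analysis (cost-effectiveness plane and acceptability curves), one-way
    and scenario analyses, an anticoagulant price-threshold search, and a
    parametric (Gompertz-Makeham) life-table generator calibrated to a
    target median survival.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
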