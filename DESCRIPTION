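Package: icdcea
Title: Markov Cohort Cost-Effectiveness Model of ICD Therapy in Heart Failure
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus Markov cohort model comparing implantable
    cardioverter defibrillator (ICD) therapy against no ICD therapy for
    primary-prevention and 1.5-primary-prevention heart-failure populations
    from the Taiwan payer perspective. Runs deterministic monthly cohort
    traces over a lifetime horizon, accrues discounted and undiscounted
    costs, life-years and QALYs, computes incremental cost-effectiveness
    ratios and net monetary benefit, and supports one-way (tornado) and
    probabilistic sensitivity analyses with beta-distributed parameters,
    cost-effectiveness acceptability curves, and a patient-level
    microsimulation used as an independent oracle for the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
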