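Package: demcua
Title: Cost-Utility Analysis of Psychotropic Deprescribing in Institutionalized Dementia Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-state (baseline health, deteriorated health, dead) Markov
    cohort model for the cost-utility analysis of a consensus-based medication
    review aimed at reducing inappropriate psychotropic prescriptions in
    institutionalized dementia patients. Provides a synthetic Gompertz-Makeham
    life-table generator, trial-survival to mortality-rate to relative-risk
    parameter derivation, a drug-cost (boxes) algorithm with a one-year cap,
    the annual-cycle Markov engine with discounted cost and QALY accumulation,
    and incremental cost-effectiveness analysis (ICER classification against a
    willingness-to-pay threshold, net monetary benefit, per-age and
    population-level cumulative incremental trajectories).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
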