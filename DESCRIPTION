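Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Analysis for Oncology Regimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a three-state partitioned survival decision model
    (progression-free, post-progression, dead) for cost-effectiveness
    analysis of oncology drug regimens. Survival curves (digitized
    Kaplan-Meier step functions or parametric) are partitioned into state
    occupancy over a fixed horizon; regimen dosing schedules, stopping
    rules, toxicity costs and health-state utilities are combined into
    expected costs, quality-adjusted progression-free life-years
    (QA-PFLYS) and QALYs, and incremental cost-effectiveness ratios.
    Includes threshold (break-even drug price) analysis, one-way and
    tornado deterministic sensitivity analysis, probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, and a
    trial-curve simulator with bundled scenario presets for immunotherapy
    regimens in advanced or recurrent endometrial cancer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
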