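Package: natar
Title: Non-Adherence Tree Analysis for Predicting Medication Non-Adherence
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fault-tree-based modelling of medication non-adherence.
    Aggregates non-adherence counts from multiple adherence studies into
    per-day event rates (NARS, NAR, NoP-weighted WNAR), represents the
    causes of discontinuation as a gated non-adherence tree (AND, OR,
    Priority-AND), derives minimal cut sets and single points of failure,
    computes closed-form non-adherence probabilities for constant-hazard
    trees, and runs a seeded time-stepped Monte Carlo cohort simulation
    with competing hazards, decaying and age-stratified rates, repairable
    supply subsystems, factor-attribution analysis and what-if
    intervention scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
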