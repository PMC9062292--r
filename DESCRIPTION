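Package: bevcea
Title: Cost-Effectiveness of a Bevacizumab Biosimilar Plus Chemotherapy in
    Advanced Nonsquamous NSCLC
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cycle-based Markov cohort model comparing first-line LY01008 (a
    bevacizumab biosimilar) combined with carboplatin/paclitaxel against
    chemotherapy alone in advanced or recurrent nonsquamous non-small cell lung
    cancer, from the Chinese healthcare system perspective. Provides Weibull
    survival extrapolation on a 3-week cycle grid with hazard-ratio adjusted
    arms, anthropometry-dependent drug acquisition costs (per-kg, per-BSA and
    Calvert dosing), discounted cost and QALY accumulation, incremental
    cost-effectiveness ratios and net monetary benefit, one-way deterministic
    sensitivity analysis with tornado ranking, probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, a real-world dosage
    scenario, and a synthetic individual-patient-data generator for
    survival-fitting and parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rlang,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    survival
Config/testthat/edition: 3
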