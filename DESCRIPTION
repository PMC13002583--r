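Package: varistrat
Title: Cost-Effectiveness of Variceal Screening Strategies in Compensated
    Advanced Chronic Liver Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus Markov cohort model comparing Baveno-based
    selective screening against universal endoscopic screening for high-risk
    varices in patients with compensated advanced chronic liver disease
    (cACLD), from the Chinese healthcare system perspective. Implements the
    full input set (diagnostic accuracy, transition probabilities, 2022 USD
    costs, health-state utilities), a deterministic five-year cohort engine
    with discounted cost and QALY accumulation, incremental cost-effectiveness
    and net monetary benefit metrics, deterministic sensitivity machinery
    (one-way sweeps, tornado ranking, bisection threshold search, two-way
    accuracy grids), probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, a Baveno VII (LSM >= 25 kPa) treatment scenario, and
    an individual-level microsimulation that serves as a stochastic oracle for
    the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
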