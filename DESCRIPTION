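Package: glaucua
Title: Markov Cohort Cost-Utility Analysis for Glaucoma Therapies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An early Markov cohort state-transition model for cost-utility
    analysis of topical therapies in open-angle glaucoma / ocular hypertension
    (OAG/OHT) with concomitant ocular surface disease (OSD). Simulates two
    treatment arms over annual cycles across seven health states (disease
    stages 0-5 plus death), accrues discounted costs by category, life-years
    and quality-adjusted life-years with half-cycle correction, and reports
    incremental cost-utility ratios and net monetary benefit. Includes one-way
    (tornado) sensitivity analysis, probabilistic sensitivity analysis with
    method-of-moments beta/gamma/Dirichlet/normal parameter distributions,
    percentile confidence intervals, and cost-effectiveness plane, acceptability
    curve and frontier construction, together with a calibrated synthetic
    parameter-set generator for testing without access to elicited study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
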