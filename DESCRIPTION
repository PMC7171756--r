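Package: cabohce
Title: Cost-Effectiveness of Second-Line Cabozantinib in Advanced
    Hepatocellular Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort (partitioned-survival) cost-effectiveness model of
    cabozantinib versus best supportive care in second-line advanced
    hepatocellular carcinoma. Fits parametric survival distributions
    (exponential, Weibull, Gompertz, log-logistic, lognormal) to digitized
    Kaplan-Meier points by least squares, extrapolates them over a lifetime
    horizon in a three-state (stable, progressive, dead) monthly-cycle cohort
    trace with 3 percent annual discounting, accrues drug, monitoring and
    adverse-event costs under German and US price scenarios, and reports
    incremental cost-effectiveness ratios against GDP-per-capita-multiple
    willingness-to-pay thresholds. Includes one-way (tornado), scenario and
    probabilistic sensitivity analyses with cost-effectiveness acceptability
    curves, plus a synthetic-data module that simulates censored survival
    times and Kaplan-Meier curves so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    jsonlite,
    optparse
Config/testthat/edition: 3
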