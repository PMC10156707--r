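Package: pptrial
Title: Bayesian Predictive-Probability Design and Analysis for Umbrella Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical engine for multi-arm phase II umbrella trials
    monitored with Bayesian predictive probability. Implements the
    beta-binomial predictive-probability design (posterior exceedance,
    interim predictive probabilities, futility/efficacy stopping
    boundaries, exact and Monte-Carlo operating characteristics,
    dropout inflation, arm expansion), derivation of confirmed best
    overall response from timestamped tumor assessments with objective
    response and disease control rates under exact Clopper-Pearson
    intervals, progression-free and overall survival derivation under
    trial-specific censoring conventions with Kaplan-Meier estimation
    and univariate Cox biomarker screens, and a synthetic umbrella-trial
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
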