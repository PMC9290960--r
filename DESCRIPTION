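Package: toxcea
Title: Cost-Effectiveness Analysis of Toxicity-Testing Methodologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparing toxicity-testing methodologies by the
    discounted cost per correct regulatory decision. Implements a lognormal
    population-risk model linking chemical potency and population exposure
    to incidence, target-risk-level decision rules (a simple accept/reject
    rule and a complex rule selecting the cheapest sufficient regulatory
    action), the decision-making value (the probability that a noisy potency
    estimate yields the same decision as perfect knowledge), and discounted
    single-chemical and program-level cost-effectiveness ratios for annually
    funded, cohort-based testing programs. Includes reference scenario
    fixtures, a log-uniform chemical population sampler, and runners that
    tabulate and plot cost-effectiveness across methodologies and decision
    rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
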