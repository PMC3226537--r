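Package: prevcea
Title: Decision-Tree Cost-Effectiveness Analysis of Primary Asthma
    Prevention in Children
Version: 1.0.0
Authors@R:
    person("Maarten", "Veld", email = "m.veld@example.org",
           role = c("aut", "cre"))
Description: A decision-analytic pipeline for evaluating primary asthma
    prevention strategies in young children from individual-level cohort
    data. Implements a rule-based objective asthma diagnosis, per-protocol
    reclassification of participants into multifaceted, unifaceted and
    control prevention groups, unit-price costing with price-year
    indexation, decision-tree construction with empirical branch
    probabilities and fold-back of expected costs and outcomes, and
    incremental cost-effectiveness analysis with dominance classification
    and a net-monetary-benefit threshold sweep. Includes a synthetic
    cohort generator with a closed-form expectation oracle for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
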