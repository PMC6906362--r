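Package: psychcooccur
Title: Co-Occurrence Interactions Among Psychological Characteristics and
    Nutritional Intervention Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A Bayesian pipeline for studying how co-occurring binary
    psychological characteristics (expressed by children and their
    guardians) associate with the outcome of a pediatric nutritional
    intervention. Provides lab-anchored outcome labeling of BMI-for-age
    z-score change, Beta-posterior baseline prevalence comparison with
    epidemiological statistics, seeded dyadic and triadic interaction
    screening with a Stay/Swap designation, per-outcome weighted
    co-occurrence networks with sixteen node-level structural metrics, and
    a gamma-prior adaptation of Bayesian Estimation (BEST) with highest
    density intervals for comparing metric distributions between outcome
    groups. A synthetic-cohort simulator with known ground truth stands in
    for private clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
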