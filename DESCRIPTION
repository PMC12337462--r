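Package: carefair
Title: Counterfactual Gender-Bias Auditing for Summarisation of Care Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing gender bias in automatic summarisation of
    free-text long-term care records ("pen portraits") under a counterfactual
    fairness design. Builds validated gender-swapped counterfactual text
    pairs, runs a pluggable summariser over a factorial design of gender,
    model and output-length cap, and quantifies bias four ways: sentiment
    differences via a linear mixed model with per-document random intercepts
    varying by summarisation model and estimated marginal gender contrasts;
    theme inclusion bias via chi-squared tests with Benjamini-Hochberg
    correction; word-level linguistic bias via a dual criterion combining
    Firth-penalised Poisson regression (with a negative-binomial fallback
    under overdispersion) and BH-adjusted chi-squared or Fisher exact counts
    tests; and a hallucination audit of medical terms absent from source
    texts. Includes a seeded synthetic-data generator producing counterfactual
    note pairs and mock summarisers with controllable injected bias, so every
    stage can be tested against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    emmeans,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
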