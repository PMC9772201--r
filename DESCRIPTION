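Package: memchoice
Title: Stimulus Memorability and Value-Based Choice: Simulation, Scoring,
    and Mixed-Model Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether stimulus memorability biases
    value-based decisions. Implements continuous-recognition stream
    construction under spacing constraints, corrected-recognition (CR)
    memorability scoring with split-half consistency against a permutation
    null, construction of rank-matched close/far two-alternative choice
    pairs, staged participant screening, conditional mixed-effects logistic
    and log-RT models with likelihood-ratio tests, Bayes factors via
    Savage-Dickey density ratios, simulation-based power analysis, and a
    drift-diffusion decomposition of choices and reaction times (Wiener
    first-passage-time likelihood, per-participant regression of drift and
    start point on trial covariates). A seeded synthetic-cohort generator
    reproduces the statistical structure of the task battery so every stage
    is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    rjags,
    coda,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
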