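Package: netcoev
Title: Stochastic Actor-Oriented Models for Co-Evolving Friendship
    Networks and Body Mass Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the co-evolution of directed friendship
    networks and ordinal body-mass-index (BMI) categories in longitudinal
    panels of co-resident college students.  Implements a stochastic
    actor-oriented model (SAOM): a continuous-time ministep Markov
    simulator in which actors toggle single ties or shift their BMI
    category by one level according to multinomial-logit evaluation
    functions; method-of-moments estimation by Robbins-Monro stochastic
    approximation with convergence diagnostics and standard errors; an
    interpretation layer producing odds ratios, alter-selection curves,
    ego-alter selection tables and Monte Carlo bootstrap confidence
    intervals; and a calibrated synthetic-study generator emulating a
    four-wave residence-hall panel with wave-specific participation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
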