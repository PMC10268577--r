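Package: enforcegame
Title: Evolution of Specialized Third-Party Enforcement in a Repeated Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a population of producers playing a prisoner's dilemma
    and specialized enforcers who tax and punish them while policing each
    other through a standing-based reputation system. Implements the
    three-step stage game (production, enforcement, meta-enforcement), the
    score automaton behind the cooperation-enforcer (CE) and parochial-
    enforcer (PE) standards, a between-period learning dynamic (logit best
    response with revision mistakes) with invariant-distribution estimation
    by long-run time averages, the exact best-reply dynamic, and closed-form
    results: equilibrium enforcer fractions, basin-of-attraction
    classification, and the stochastic-stability criterion. A compiled
    engine makes million-period runs fast; results come back as tibbles with
    ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
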