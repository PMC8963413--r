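Package: panicabm
Title: Agent-Based Simulation of Panic Buying and Social Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded, configurable multi-agent Monte Carlo simulator of
    panic-buying contagion during a sudden public-health crisis. Agents on a
    Barabasi-Albert scale-free interaction network carry material and safety
    needs, panic emotion, conformity, and a threshold buying attitude; a
    shared material stock depletes as agents buy. Five social-intervention
    mechanisms (supply monitoring, information review, information guidance,
    official response, psychological counseling) are composable, independently
    switchable effects with strengths, trust weights and time delays. An
    experiment harness reproduces need-level scenario grids, single- and
    combined-intervention studies, random-needs sweeps, and real-world case
    parameterizations, returning tidy tibbles ready for dplyr and ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
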