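Package: sepstates
Title: Sepsis State Discovery and Progression Modelling from ICU Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers extremal disease states in multivariate ICU time
    series by archetypal analysis (alternating simplex-constrained least
    squares), validates the states with multivariate two-sample tests
    (Box's M, Hotelling T-squared), ranks discriminative clinical
    variables by inertia-based quality indices and a variation test,
    scores per-state expression of seven organ-system functions, profiles
    comorbidity enrichment by z-scores, and models state-transition
    dynamics with higher-order Markov chains on de Bruijn graphs,
    including gradient archetypes for transition-marker identification.
    A seeded synthetic-cohort generator emulates the peri-onset sepsis
    cohort structure (42 clinical variables on a 4-hour grid) so every
    stage is testable without access to restricted clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
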