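Package: adaptivesis
Title: Adaptive SIS Epidemics on Rewiring Networks with Heterogeneous Susceptibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying susceptible-infected-susceptible (SIS)
    epidemics on adaptive contact networks whose agents differ in intrinsic
    susceptibility and avoid contact with infected neighbours by rewiring.
    Provides an event-driven (Gillespie) stochastic simulator for the
    two-type rewiring SIS process on Erdos-Renyi and user-supplied networks,
    the pair-approximation moment-closure system of eleven ordinary
    differential equations, pseudo-arclength continuation of equilibrium
    branches with fold and transcritical detection (persistence threshold,
    initial and adapted invasion thresholds), and closed-form mean-field
    predictions of the self-organized degree heterogeneity, including the
    link reproductive number and its optimal degree ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
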