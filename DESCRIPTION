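Package: iitsim
Title: Stochastic Simulation of Incompatible Insect Technique Programs with
    Bi-Directional Wolbachia Incompatibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time Markov population-process model of Aedes
    albopictus under competing Wolbachia strains, with bi-directional
    cytoplasmic incompatibility, age-related decay of incompatibility in
    wild-type males, density-dependent recruitment, and wild-type
    immigration and emigration. Provides an exact Gillespie simulator and a
    tau-leaping approximation, in silico cage trials for estimating the
    unstable equilibrium threshold of establishment of a released strain,
    and incompatible-insect-technique release policies (naive, complete
    stop, maintain) evaluated for suppression success, reversibility, and a
    released-insect cost proxy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
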