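Package: idnetgame
Title: Evolutionary Games on Interdependent Lattices with Social Influence
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Monte Carlo simulator for the evolution of cooperation on two
    interdependent square lattices, one carrying the snowdrift game and the
    other the prisoner's dilemma. Players update asynchronously either by
    social influence (copying the majority strategy of their interlayer
    partner group) with probability s, or by Fermi-rule imitation of a
    random local neighbor. Provides a compiled simulation engine, cooperation
    and interlayer strategy-pair observables, parameter sweeps, phase
    diagrams, threshold (phase-transition) detection, exact small-lattice
    update enumeration for validation, and plain-text result serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
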