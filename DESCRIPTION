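Package: spovsim
Title: Individual-Based Simulation of Sexually Cannibalistic Female
    Strategies on an X-Linked Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time, individual-based simulation of the evolution
    and coexistence of two female behavioral types in a wolf-spider-like
    life history: aggressive-spillover strategies (SPOV and variants), in
    which females attack approaching males regardless of mating or hunger
    state, and a plastic "mate first, cannibalize later" (MFCL) strategy.
    Behavior is controlled by a single locus on an XX/X0 sex-determination
    system. The package provides a daily within-season mating/cannibalism
    engine (compiled for speed, with a plain-R reference implementation),
    end-of-season fecundity allometries, differential juvenile survival,
    maintenance and invasion experiments across generations, parameter
    sweeps, and post-hoc statistics that diagnose frequency-dependent
    selection in oscillating allele-frequency trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    emmeans
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
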