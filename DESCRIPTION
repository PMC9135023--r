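Package: quadgait
Title: Work-Minimizing Trajectory Optimization of Planar Quadrupedal Walking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory optimization of periodic, symmetric walking gaits for a
    planar quadruped modelled as a rigid trunk with massless telescoping limbs.
    Gaits are found by direct collocation with contact-invariant complementarity
    constraints and a multi-start augmented-Lagrangian solver, minimizing one of
    three mechanical work objectives: Net Centre-of-Mass Work, Individual Limbs
    Centre-of-Mass Work, or Limb Extension Work, under point-mass or
    distributed-mass trunk models. Post-processing computes work breakdowns,
    pendular (Cavagna) recovery, gait diagrams, duty factors, and footfall
    pattern classification, and ships a Warmblood horse parameter preset plus
    conservative toy systems (pendula, rolling ball, passive four-bar vaulting)
    used as analytic validation oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, yaml, deSolve, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
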