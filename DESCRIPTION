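Package: condensaxs
Title: RNA Conformational Ensembles and Condensate Dynamics from Solution Scattering and Coarse-Grained Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying single-stranded RNA conformations inside
    ribonucleoprotein coacervates. Builds all-atom RNA conformers from
    dinucleotide torsion-angle suites, computes Debye-formula small-angle
    X-ray scattering with Guinier, molecular-form-factor (Flory exponent),
    Kratky, match-point and I(0) analyses, selects scattering-consistent
    sub-ensembles with a genetic algorithm plus iterative suite reweighting
    (Jensen-Shannon convergence), quantifies chain order (orientation
    correlation functions, base stacking), runs residue-level coarse-grained
    Langevin dynamics with Debye-Hueckel electrostatics and Wang-Frenkel
    sticker potentials, and analyses condensate trajectories (clustering,
    exchange events, convex-hull shape fluctuation, chain shape metrics).
    A synthetic-data module generates structures, noisy profiles and
    scripted trajectories with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    bio3d,
    igraph,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
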