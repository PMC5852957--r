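Package: msmflux
Title: Markov State Models and Transition-Path Flux Analysis of Trajectory Ensembles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative kinetic analysis of ensembles of molecular
    dynamics trajectories: residue contact maps and charged-pair interaction
    strengths, gate-distance time series with trajectory-bootstrap broken
    fractions, population free-energy projections with block-bootstrap errors,
    time-lagged independent component analysis (tICA), Markov state model
    estimation with implied-timescale validation, PCCA+ macrostate lumping, and
    transition-path-theory committor, flux and pathway decomposition. Includes
    stochastic generators (Markov chains, Gaussian emissions, overdamped
    Langevin dynamics, and a labelled bead-model ion-release system) that
    produce trajectory ensembles with known kinetic ground truth, so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'features.R'
    'free-energy.R'
    'io.R'
    'msm.R'
    'msmflux-package.R'
    'pcca.R'
    'tpt.R'
    'tica.R'
    'synthetic.R'
    'pipeline.R'
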