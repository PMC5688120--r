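Package: kinemsm
Title: Markov State Modelling of Kinase Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring the thermodynamics and kinetics of protein
    conformational ensembles from trajectory data: structural featurization
    (dihedrals, contact distances, RMSD order parameters), time-lagged
    independent component analysis (tICA) with kinetic mapping, K-means
    discretization, reversible maximum-likelihood Markov state model (MSM)
    estimation with spectral analysis, kinetic Monte Carlo trajectory
    synthesis, mean first passage times, and trajectory-level bootstrap
    confidence intervals.  Ships a synthetic-data module that generates
    metastable discrete-state dynamics with Gaussian feature emissions,
    calibrated to the four-state landscape (active, intermediate, Src-like,
    DFG-out) of the BTK kinase domain and its protonation-dependent
    perturbation, so the full pipeline can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    igraph,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
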