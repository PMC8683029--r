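Package: ahremd
Title: Adaptive Hamiltonian Replica Exchange with Gaussian-Mixture Bias
    Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Implements an adaptive Hamiltonian replica-exchange (H-REMD)
    sampler in which each replica carries a bias potential proportional to a
    Gaussian-mixture fit of recently sampled collective-variable (CV)
    distributions, refit on a sliding window at fixed intervals so that the
    bias iteratively destabilizes the currently sampled region.  The package
    provides desk-scale model systems (1D double well, harmonic well,
    Mueller-Brown surface, coarse-grained domain bead models) with a BAOAB
    Langevin propagator, center-of-mass distance collective variables with
    analytic gradients, a seeded univariate Gaussian-mixture EM fitter, the
    replica-exchange orchestration with Metropolis configuration swaps, and
    the companion analysis protocol: Boltzmann-inversion free-energy profiles
    with block-bootstrap error bands, RMSF with optional rigid-body
    superposition, density-based (DBSCAN) conformational clustering with
    sieved frame assignment, and a bias-convergence diagnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
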