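Package: exgmerge
Title: Ex-Gaussian Intensity Diagnostics and Ideal Crystal Merging for Serial Crystallography
Version: 0.1.0
Authors@R: person("exgmerge", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Per-reflection intensity-distribution analysis for serial
    femtosecond crystallography. Reads unmerged Bragg observation lists,
    maps observations to the asymmetric unit of an orthorhombic P2(1)2(1)2(1)
    lattice, fits Gaussian and exponentially-modified Gaussian (ex-Gaussian)
    models to each reflection's intensity histogram by maximum likelihood,
    applies a nested likelihood-ratio test with resolution-shell diagnostics,
    and merges reflections with a Bayesian "Ideal Crystal" rule: Metropolis
    MCMC over ex-Gaussian parameters under uniform priors, reporting the
    posterior mean and standard deviation of the intensity at which each
    sampled distribution's cumulative distribution function reaches a
    critical value. Includes Wilson-plot B-factor estimation, a
    resolution-dependent correction factor, and a synthetic-data generator
    that emulates SFX and synchrotron observation statistics.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    optparse,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
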