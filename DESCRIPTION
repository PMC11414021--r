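Package: fibrildyn
Title: Monomer-Fibril Exchange, Fibril Stability and Aggregation Kinetics
Version: 0.1.0
Authors@R:
    person("Fibrildyn", "Maintainers", email = "maintainers@fibrildyn.org",
           role = c("aut", "cre"))
Description: Quantitative analysis toolkit for functional-amyloid systems
    such as the E. coli curli subunit CsgA. Implements a two-site
    (free monomer / fibril-bound dark state) Bloch-McConnell model for
    dark-state exchange saturation transfer (DEST) profiles, with matrix
    exponential and adaptive ODE propagators and a least-squares fitter for
    the dissociation rate; mono-exponential CPMG R2 and inversion-recovery
    R1 relaxation fitting and the delta-R2 estimator of the apparent
    association rate; a two-state formic-acid dissolution model yielding
    the midpoint FA50, the m-value and the dissolution free energy;
    sigmoidal feature extraction (lag time, growth rate, plateau) from
    thioflavin T traces and elongation rates from single-fibril TIRF
    length series; plus seeded synthetic-data generators and a pipeline
    front end so the whole analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
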