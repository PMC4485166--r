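Package: neurofield
Title: Metastable Dynamics in Heterogeneous Neural Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construct heterogeneous synaptic kernels of the Amari neural
    field equation directly from prescribed metastable spatial patterns and
    Lotka-Volterra winnerless-competition dynamics, without supervised
    training. Provides design and verification of stable heteroclinic
    contours, Pincherle-Goursat (finite-rank) two- and three-point kernel
    construction with biorthogonal adjoint modes, stiff integration of the
    expanded field equation, order-parameter projection and reconstruction,
    synthetic event-related-potential trial ensembles with observational
    noise and grand averaging, and deterministic grayscale digit fixtures
    for two-dimensional distributed-representation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
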