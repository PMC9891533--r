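Package: spheroidgeom
Title: Geometric Identifiability Analysis for Tumour Spheroid Growth Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hierarchy of tumour-spheroid growth models (logistic, bounded
    Gompertz, Richards, radial-death, Greenspan, and a simplified Ward-King
    moving-boundary multiphase model), together with classical practical
    identifiability analysis (maximum likelihood fitting, AIC, profile
    likelihood, Fisher information and sloppiness spectra) and a geometric
    between-model analysis: a least-squares map from the parameters of a
    complex, possibly non-identifiable model to those of a simple identifiable
    surrogate, its Jacobian and relative sensitivity matrix, constant-feature
    manifolds in parameter space, sloppy-direction paths, and feature-steering
    parameter moves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
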