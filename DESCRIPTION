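Package: sexqg
Title: Sex-Specific Quantitative Genetics via Bayesian Animal Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pedigree-based Bayesian animal models with a cross-sex additive
    genetic covariance structure, fitted by Gibbs sampling. Partitions
    phenotypic variance into sex-specific additive genetic, common
    environment/maternal, permanent environment, contest and residual
    components, and derives heritabilities, cross-sex genetic correlations,
    mean-standardized evolvability coefficients and female-minus-male
    posterior contrasts with MCMC convergence diagnostics. Includes pedigree
    parsing and additive (numerator) relationship matrix construction with
    inbreeding, a synthetic-data generator emulating a paired full-sib
    breeding design with assortative mating, right-censored latency traits
    and dyadic aggression contests, and an end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
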