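Package: felhip
Title: Quantitative Genetics of Hip Dysplasia Screening Programmes in Cats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ordinal hip-dysplasia screening data from
    pedigree cat breeding programmes. Provides pedigree handling (inbreeding,
    additive relationship matrix and its sparse inverse, generations-of-screening
    ancestor scores), demographic score summaries and laterality, sex- and
    age-adjusted residual body mass from Gompertz growth curves, right-truncated
    Poisson regressions for selection response, and Bayesian threshold animal
    models (univariate and bivariate) giving heritability on the latent and
    observed scales and genetic correlations. Includes a synthetic
    breeding-programme simulator with known genetic truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    MASS,
    nnet,
    minpack.lm,
    truncnorm,
    statmod,
    coda,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
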