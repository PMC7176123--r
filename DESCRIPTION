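Package: mcarmap
Title: Joint Bayesian Multivariate Disease Mapping for Cardiovascular
    Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Small-area joint disease mapping of correlated binary health
    outcomes at health-district level. Implements clinical outcome
    derivation from survey measurements and self-reports, design-weighted
    prevalence estimation with linearised confidence intervals, the South
    African Multidimensional Poverty Index (headcount times intensity) and
    its district quintiles, and a multivariate intrinsic conditional
    autoregressive (MCAR) convolution logistic model fitted by
    Polya-Gamma augmented Gibbs sampling, together with a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
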