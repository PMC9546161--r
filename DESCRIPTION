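Package: selgrad
Title: Selection Gradients from Log-Linear and Log-Quadratic Fitness Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical conversion between the coefficients of exponential
    (log-linear and log-quadratic) fitness functions and directional and
    quadratic selection gradients under multivariate normal phenotypes,
    including the post-selection phenotype distribution, the Gaussian
    fitness-function equivalence, and first-order (delta-method) propagation
    of coefficient (co)variances into gradient uncertainty. Provides log-link
    GLM and Lande-Arnold ordinary-least-squares estimation front ends for
    individual-level trait-fitness data, case-bootstrap standard errors, a
    numerical-averaging estimator, and a seeded simulation framework for
    studying estimator bias, standard-error calibration, and mean squared
    error.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
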