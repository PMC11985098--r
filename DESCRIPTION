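Package: gradspline
Title: Gradient-Augmented Smoothing Spline ANOVA Regression via Random
    Fourier Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric estimation of a multivariate function from noisy
    function values together with noisy first-order partial derivatives, in the
    tensor-product smoothing spline ANOVA framework.  The estimator expands the
    function in random Fourier features sampled from the spectral density of a
    shift-invariant kernel, augments the design with analytic feature
    derivatives so that gradient observations enter the least-squares loss
    directly, solves the resulting weighted ridge problem in primal or dual
    (factorized Gram) form, and selects the penalty by generalized
    cross-validation.  An exact kernel-representer solver provides a
    small-sample oracle, a stochastic-kriging baseline supports comparison
    experiments, and built-in simulators generate option-pricing data with
    infinitesimal-perturbation-analysis gradients, Cobb-Douglas cost data, and
    ion-channel computer-model data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
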