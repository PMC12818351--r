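Package: bicepsfm
Title: Forward-Model Parameterization with Bayesian Inference of
    Conformational Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint Bayesian inference of conformational populations,
    uncertainty nuisance parameters, and forward-model parameters (Karplus
    coefficients or a small neural network) from ensemble-averaged scalar
    J-coupling data.  Provides replica-averaged Gaussian, Good-Bad and
    multi-severity Good-Bad likelihood models robust to outlier
    measurements, Markov chain Monte Carlo posterior sampling with
    gradient-informed proposals, a free-energy model-selection score
    estimated with the multistate Bennett acceptance ratio over a schedule
    of restraint strengths, variational minimization of that score with
    L-BFGS-B, a regularized singular-value-decomposition baseline fit with
    jackknife uncertainties, and a synthetic toy-data generator emulating
    protein backbone dihedral ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
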