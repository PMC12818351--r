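# bicepsfm

Forward-model parameterization with Bayesian inference of conformational
populations.

NMR scalar couplings are predicted from backbone dihedral angles through the
Karplus relation

    3J(phi) = A cos^2(phi + phi0) + B cos(phi + phi0) + C

whose coefficients must be calibrated against experimental couplings that
are ensemble-averaged, noisy, and contaminated by systematic errors.
`bicepsfm` is for structural-biology and molecular-simulation researchers
who want to calibrate such forward models *jointly* with the conformational
populations of the ensemble used to calibrate them, instead of assuming a
fixed reference structure.

The package implements:

* **Replica-averaged Bayesian reweighting** — `N` replicas sample
  conformational states so that the averaged prediction
  `g_j = (1/N) sum_r g_j(X_r, theta)` is restrained toward each observed
  coupling `d_j`, with the data term multiplied by `N` (the
  maximum-entropy-consistent restraint strength).
* **Outlier-robust likelihoods** — a Good–Bad model in which each
  observable is an equal-weight mixture of a "good" Gaussian of width
  `sigma0 = sqrt(sigma_B^2 + sigma_SEM^2)` and a "bad" one of width
  `phi * sigma0`, with the bad fraction marginalized analytically; plus
  Gaussian and multi-severity variants.  Scale nuisances carry truncated
  Jeffreys priors and are sampled.
* **MCMC posterior sampling** of states, nuisances and Karplus
  coefficients, with gradient-informed proposals during burn-in
  (`theta' = theta - lrate * grad_u + eta * z`) and a robust warm start.
* **A free-energy model-selection score** — the free energy of switching
  the experimental restraints on (`xi = 0 -> 1`), estimated with the
  multistate Bennett acceptance ratio over a (optionally
  thermodynamic-length-optimized) `xi` schedule, with gradients and
  Hessian- or multi-start-based parameter uncertainties.
* **Variational optimization** of the coefficients by L-BFGS-B on that
  score, with common-random-number objective evaluations.
* **An SVD baseline** (regularized pseudo-inverse fit with jackknife
  uncertainties) and a **synthetic toy-data generator** emulating protein
  backbone dihedral ensembles with random plus systematic experimental
  error.
* **A neural-network forward model** (periodic angle embedding, one
  GELU hidden layer) trained with the restrained-ensemble energy as loss.

## Worked example

Generate a synthetic 100-state, 60-coupling dataset with 0.4 Hz noise,
recover the Karplus coefficients with Good–Bad posterior sampling, and
compare with the SVD baseline:

```r
library(bicepsfm)

ds <- build_toy_dataset(n_states = 100, n_obs = 60, seed = 1)   # truth A=6.51, B=-1.76, C=1.60
ds <- add_noise(ds, sigma_data = 0.4, seed = 2)

trace <- run_chain(ds$ensemble, ds$J_obs, sampler_config(seed = 3),
                   likelihood = "good_bad", init_theta = c(0, 0, 0))
marginal_summary(trace)
#>   parameter type       mean          sd        map
#> 1         A   3J  5.8993618 0.052821481  5.8904624
#> 2         B   3J -1.5932221 0.027619187 -1.5830425
#> 3         C   3J  1.7152122 0.010894570  1.7205539
#> 4   sigma_B   3J  0.1006058 0.000609212  0.1000904
#> 5       phi   3J  3.2488243 0.090930266  3.2481001

rmse_curve(ds, posterior_theta(trace))
#> [1] 0.1062  # Hz, ensemble-averaged couplings under estimate vs truth

sv <- svd_fit_dataset(ds, seed = 4)
rmse_curve(ds, sv$theta)
#> [1] 0.1402
```

The summary rows are the marginal posteriors: the coefficient estimates
with their uncertainties, the inferred experimental uncertainty `sigma_B`
(here pinned near its 0.1 Hz floor because the replica-averaged model
absorbs part of the 0.4 Hz noise), and the outlier-severity scale `phi`.
The curve RMSE compares ensemble-averaged couplings under the estimated and
true coefficients over the 60 observables; the Bayesian estimate beats the
population-weighted SVD fit on the same data.

Model comparison uses the restraint-switching free energy (lower is better
agreement with the data, all error sources integrated out):

```r
compute_score(ds$ensemble, ds$J_obs, posterior_theta(trace),
              config = sampler_config(n_burn = 1000, n_steps = 4000, seed = 5))
```

A thin command-line wrapper lives in `exec/bicepsfm` with subcommands
`simulate`, `sample`, `optimize`, `score`, `svd-fit`, `train-nn` and
`validate`; all inputs are plain CSV/YAML and outputs are CSV/JSON with a
run manifest.

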