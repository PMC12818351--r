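---
title: "Forward-model parameterization with Bayesian inference of conformational populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward-model parameterization with Bayesian inference of conformational populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Vicinal scalar couplings report on backbone dihedral angles through the
empirical Karplus relation

$$ {}^3J(\phi) = A\cos^2(\phi + \phi_0) + B\cos(\phi + \phi_0) + C , $$

with one coefficient set $(A, B, C)$ and a fixed phase $\phi_0$ per coupling
type.  The coefficients are not known from first principles; they are fitted
against reference data whose dihedral angles are themselves uncertain and
dynamically averaged.  `bicepsfm` treats this as a joint Bayesian inference:
given a conformational ensemble (states $X$ with prior populations $p(X)$)
and ensemble-averaged experimental couplings $d_j$, it simultaneously infers

* the conformational populations, through $N$ replicas whose states are
  sampled so that the replica-averaged prediction
  $\bar g_j = \frac1N \sum_r g_j(X_r, \theta)$ is restrained toward $d_j$
  (the maximum-entropy-consistent replica-averaging construction),
* the error model, through nuisance parameters described below, and
* the forward-model parameters $\theta = (A, B, C)$ themselves, either by
  including them in the posterior (MCMC) or by variational minimization of a
  free-energy score.

## The likelihood models

Each observable carries a total uncertainty
$\sigma_0 = \sqrt{(\sigma^B)^2 + (\sigma^{SEM}_j)^2}$, combining a sampled
Bayesian uncertainty $\sigma^B$ (one per observable type) with the
finite-replica error $\sigma^{SEM}_j$ of the averaged prediction.  The
default estimate of $\sigma^{SEM}_j$ is the population standard deviation of
the per-replica predictions divided by $\sqrt N$, so it decreases as the
square root of the replica count; the two alternative normalizations are
available through `sampler_config(sem_mode=)` because the literature is not
unambiguous about the convention.

The *Gaussian* model is the ordinary replica-averaged likelihood; the full
energy (negative log posterior) multiplies the per-observable data term by
$N$, the replica-averaging restraint-strength convention.

The *Good-Bad* model assumes most observables carry the typical uncertainty
while a few ("bad" measurements, systematic errors) carry an inflated one,
$\varphi\sigma_0$ with $\varphi \ge 1$.  Marginalizing the unknown bad
fraction uniformly over $[0, 1)$ and the per-observable uncertainty against
the two-point prior gives the per-observable likelihood

$$ L_j = \tfrac12\,\mathcal N(d_j \mid \bar g_j, \sigma_0^2)
       + \tfrac12\,\mathcal N(d_j \mid \bar g_j, \varphi^2\sigma_0^2), $$

an equal-weight scale mixture of two properly normalized Gaussians, gated by
Heaviside factors that switch a component off if its width falls below the
finite-sampling error (with the convention $H(0) = 0$, so the gates stay
open at the boundary).  At $\varphi = 1$ the model is exactly Gaussian.  We
note that carrying an *extra* $1/\varphi$ on the wide component (so that its
weight is $1/(2\varphi)$, a form that appears in parts of the literature)
double-counts the normalizer already inside the wide density; with that
weighting the wide component can never out-compete a single inflated
Gaussian for 2-4 Hz outliers riding on 0.5-1 Hz noise, and the model loses
precisely the robustness it exists to provide.  The equal-weight form is
also the two-component case of the multi-severity generalization
(`multiseverity_energy()`), which replaces the single inflator by levels
$\varphi_1 = 1 < \varphi_2 < \dots < \varphi_M$ with Dirichlet-marginalized
equal weights $1/M$.

Scale nuisances get truncated Jeffreys priors (uniform in $\log\sigma^B$ and
$\log\varphi$).  The default support $\sigma^B \in [0.1, 10]$ Hz encodes the
typical precision of NMR frequency measurements; the floor also plays a
structural role, discussed under *Known limitations*.

The energy gradient in $\theta$ used everywhere is

$$ \frac{\partial u}{\partial \theta_i}
   = -N \sum_j \frac{\partial \bar g_j}{\partial \theta_i}\,
     w_j\,\frac{d_j - \bar g_j}{\sigma_0^2}, \qquad
   w_j = \frac{r_{1j} + r_{2j}/\varphi^2}{r_{1j} + r_{2j}}, $$

where $r_{1j}, r_{2j}$ are the mixture responsibilities: observables
absorbed by the wide component pull on $\theta$ a factor $\varphi^2$ more
weakly.  Like the underlying published form, this is the partial derivative
at fixed $\sigma^{SEM}$; the dependence of the finite-sampling error on
$\theta$ is deliberately not differentiated (and the sampler's $\theta$
moves likewise hold the cached $\sigma^{SEM}$ fixed), which closes a
degenerate channel where inflating the coefficients inflates the error bars.

## Posterior sampling

`run_chain()` performs one composite sweep per step: `n_replicas`
uniform-proposal replica-state moves, then per observable type a log-space
random walk in $\sigma^B$, one in $\varphi$, a correlated
($\sigma^B\!\downarrow, \varphi\!\uparrow$) "trade" move along the
degenerate direction that separates the sloppy-Gaussian and
tight-plus-outlier basins, and a $\theta$ move.  Because the Jeffreys priors
are uniform in log scale, the log-space proposals' Jacobians cancel the
prior terms and the acceptance ratios carry only the data term.

During burn-in, $\theta$ proposals are gradient-informed,
$\theta' = \theta - l_{rate}\nabla u + \eta z$; after burn-in the gradient
is turned off and a symmetric random walk (with a 10% fraction of 5x
strides for sub-mode hopping) keeps the production kernel reversible, so no
Hastings correction is needed for the recorded samples.  The head of
burn-in is a *robust warm start*: the outlier component is held wide open
($\varphi$ pinned high) and $\sigma^B$ tracks a median-absolute-residual
scale while $\theta$ descends.  Without it, chains started far from the
optimum pass through a regime where $\sigma^B$ inflates to cover the
transient misfit, $\varphi$ collapses to 1, and the sampler settles in the
non-robust Gaussian basin; the warm start routes it to the robust basin,
and everything it does is discarded with the rest of burn-in.

Default protocol (mirroring the published toy study): 32 replicas, 10k
burn-in, 50k production steps.

## The free-energy score

Model quality is the free energy of switching the experimental restraints
on: likelihoods are tempered as $[p(D \mid X, \sigma)]^{\xi}$, the energy is
affine in $\xi$ ($u_\xi = u_{prior} + \xi\,u_{data}$), and
$f(\theta) = -\ln Z(\theta)/Z_0$ is estimated from chains run at a schedule
of $\xi$ values with the multistate Bennett acceptance ratio (`mbar()`,
damped-Newton solution of the convex MBAR objective, tolerance $10^{-8}$,
asymptotic covariance from the weight-matrix SVD).  Samples are thinned by
the integrated autocorrelation time of the tempered energy before entering
MBAR.  Because the score is extensive in the replica count, results are
also reported reduced, $f/N$.  The default schedule has 11 uniformly spaced
$\xi$ values; `optimize_xi_schedule()` re-spaces them equidistantly in
thermodynamic length, approximating the metric by the per-state standard
deviation of the data energy from a pilot run (5k steps per state by
default) integrated by trapezoid.

The score gradient is the restrained-ensemble average of
$\partial u/\partial\theta$ at $\xi = 1$, recorded per sample by the
sampler.  Its C-component is exact; the A and B components inherit the
fixed-$\sigma^{SEM}$ convention above, so they agree with the
restrained-ensemble average rather than with the total derivative of $f$ --
a deliberate, published convention, verified against exact enumeration in
the tests.

`hessian_uncertainty()` inverts a finite-difference Hessian of the score
gradient for parameter covariances near a minimum and refuses
non-positive-definite input, in which case the dispersion of independent
optimization starts (`multistart_uncertainty()`) is the honest estimate.

## Variational optimization

`minimize_score()` runs bounded L-BFGS-B on the stochastic score.  Within
one optimization round every evaluation reuses one RNG seed (common random
numbers), so the line search sees a deterministic surface; rounds re-seed
and restart from the current iterate, letting searches stalled by one noise
realization progress on the next.  Four replicas and 10k MC steps per
evaluation are the defaults, as in the published comparison.  The score
surface has a long, nearly flat valley along the correlated
$(A, B)$-direction (the same near-collinearity that limits the SVD
baseline), and distant starts can stall inside it; the cross-start
dispersion reports exactly this.

## The synthetic-data generator

`build_toy_dataset()` emulates a protein backbone.  Each observable (a
"residue") draws a center angle from the three-mode Gaussian mixture over
$\phi$ -- beta sheet $(-110^\circ, 20^\circ, w{=}0.35)$, right-handed helix
$(-60^\circ, 10^\circ, w{=}0.5)$, left-handed helix
$(60^\circ, 5^\circ, w{=}0.15)$ -- and each conformational state carries
that center plus independent Gaussian jitter of `sigma_state` degrees
(default 10, a typical within-secondary-structure spread across a
conformational ensemble: clearly smaller than the sheet-mode width, larger
than libration).  This two-level structure is essential: if instead every
state/observable angle were an independent mixture draw, all
ensemble-averaged design rows would collapse onto the same mixture moments
and the three coefficients would be unidentifiable beyond the mean coupling
level, which contradicts the precision any published fit attains.  Clean
observables are plain means over states -- the states are themselves
mixture draws, so equal weights are the correct discretization of the
ensemble average (density re-weighting would double-count the density; it
is kept as an option).  The sampling prior handed to inference is uniform;
recovering population structure is the reweighting machinery's job.

`add_noise()` adds iid Gaussian noise of SD `sigma_data` and shifts a
uniformly drawn count (up to 20% of observables) by $+U(2, 4)$ Hz,
emulating systematic error; every draw is logged.  `perturb_prior()`
degrades the ensemble itself by re-jittering all angles, for
score-vs-quality studies.  What the generator does *not* emulate: coupled
backbone torsions, state-to-state correlation structure, multiple coupling
types in one dataset (supported by the machinery, not exercised by the
toy), or non-Gaussian experimental error beyond the one-sided shifts --
passing tests on this toy say nothing about those features of real data.

## The neural-network forward model

`nn_predict()` implements a 2-200-1 fully connected network with GELU
activations on the periodic embedding $x = (\cos\phi, \sin\phi)$ and
LeCun-normal initialization; `train_nn()` trains it with Adam (learning
rate $10^{-3}$, 2000 epochs) using the restrained-ensemble energy as loss.
Every 10 epochs a short MCMC refresh (500 steps) re-samples the nuisance
parameters and replica configurations at fixed weights; between refreshes
the weight gradient averages the per-configuration residual gradients over
the sampled restrained ensemble (the score-gradient contract, with
$\partial \bar g/\partial w$ from backpropagation).  The training replica
count defaults to 16: with very few replicas over a five-state ensemble the
occupancy resolution (1/4) injects sampling artifacts that put a floor
under the pointwise accuracy.  On noisy data the network, unlike the rigid
three-parameter Karplus form, has enough effective freedom to follow noise
in the 60 averaged constraints; the nuisance sampling moderates but does
not eliminate this, so its noisy-data pointwise error is expected to sit
above the parametric refit's.

## Numerical choices

* MAP estimates use the highest-density histogram bin, Freedman-Diaconis
  widths with a floor of 30 bins.
* MBAR: self-consistent/Newton iteration to relative tolerance $10^{-8}$,
  at most $10^4$ iterations; an error names the worst-overlap pair.
* Degenerate inputs: collapsed prior bounds are treated as pinned
  parameters (their normalizers are dropped); initial nuisance values are
  clamped into bounds; zero replica-prediction variance gives
  $\sigma^{SEM} = 0$ with gates open.
* Problem sizes in the tests and acceptance script are the published
  protocol (100 states x 60 observables, 32 replicas, 10k + 50k steps;
  5-state NN dataset with 2000 epochs) with trial counts of 10 per noise
  level and 50 prior perturbations -- enough for the reported averages to
  be stable at the tolerance of interest.

## Known limitations

* **Robustness ceiling.** An unbiased least-squares fit of 3 coefficients
  to 60 averaged couplings with noise $\sigma$ has expected curve-RMSE
  $\sigma\sqrt{3/60} \approx 0.22$ Hz at $\sigma = 1$ Hz.  Mean recoveries
  materially below that require the population reweighting to absorb most
  of the random noise; in a 100-state ensemble that absorption capacity
  grows with the coefficient scale, creating a degenerate incentive to
  inflate the coefficients until the systematic outliers also become
  absorbable.  The implementation therefore tracks the published
  low-noise behavior closely but its high-noise mean recovery error grows
  roughly with the least-squares floor rather than staying flat.
* **Outlier-assignment multimodality.** At `sigma_data` $\gtrsim 0.5$ Hz
  the Good-Bad posterior develops near-degenerate sub-modes differing in
  which observables the wide component absorbs; single-site MCMC does not
  tunnel between them within 50k steps, so independent chains can report
  stable coefficient means a few hundredths of a Hz apart (visible as
  inflated Gelman-Rubin statistics).  Pooling chains from distinct starts,
  as all reported estimates do, is the practical mitigation.
* The score gradient's fixed-$\sigma^{SEM}$ convention makes L-BFGS-B
  minimize a slightly different functional than the exact score along the
  $A, B$ directions; at the minima encountered in practice the discrepancy
  is well inside the multi-start dispersion.
* The ubiquitin-scale application (six coupling types, hundreds of
  observables, external structural ensembles) is supported by the input
  formats and per-type machinery but not validated here beyond synthetic
  smoke data.
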