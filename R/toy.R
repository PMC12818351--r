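#' Multi-modal dihedral mixture specification
#'
#' Gaussian mixture over backbone dihedral angles emulating secondary
#' structure: by default beta sheet (mu = -110 deg, sd = 20 deg, w = 0.35),
#' right-handed helix (-60, 10, 0.5) and left-handed helix (60, 5, 0.15).
#'
#' @param mu,sd,w mode means (degrees), standard deviations (degrees) and
#'   weights (weights are normalized to sum to 1).
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(mu = c(-110, -60, 60), sd = c(20, 10, 5),
                         w = c(0.35, 0.5, 0.15)) {
  if (length(mu) != length(sd) || length(mu) != length(w))
    stop("mu, sd, w must have equal lengths", call. = FALSE)
  if (any(sd <= 0) || any(w < 0) || sum(w) <= 0)
    stop("invalid mixture specification", call. = FALSE)
  structure(list(mu = mu, sd = sd, w = w / sum(w)), class = "mixture_spec")
}

wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180   # keep (-180, 180]
  y
}

#' Mixture density over angles (degrees)
#' @param phi angles in degrees.
#' @param spec a [mixture_spec()].
#' @export
mixture_density <- function(phi, spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  dens <- 0
  for (l in seq_along(spec$w))
    dens <- dens + spec$w[l] * stats::dnorm(phi, spec$mu[l], spec$sd[l])
  dens
}

#' Sample dihedral angles from a multi-modal mixture
#'
#' Draws the mode with probability `w_l`, then a Gaussian angle
#' `(mu_l, sd_l)`; angles are wrapped into (-180, 180].
#'
#' @param n number of draws.
#' @param spec a [mixture_spec()].
#' @param seed optional RNG seed.
#' @return angles in degrees, with the drawn mode index attached as
#'   attribute `"component"`.
#' @export
sample_phi_mixture <- function(n, spec = mixture_spec(), seed = NULL) {
  stopifnot(inherits(spec, "mixture_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(spec$w), n, replace = TRUE, prob = spec$w)
  out <- wrap_angle(stats::rnorm(n, spec$mu[comp], spec$sd[comp]))
  attr(out, "component") <- comp
  out
}

#' Build a synthetic toy dataset
#'
#' Emulates a protein backbone: each observable (a "residue") has a center
#' angle drawn from the multi-modal mixture, and each conformational state
#' carries that angle plus independent Gaussian structural heterogeneity of
#' SD `sigma_state` degrees, so observables probe distinct dihedral regions
#' while states supply genuine ensemble variation.  Clean ensemble-averaged
#' couplings are computed under the true Karplus model.  With the default
#' `weighting = "uniform"` the ensemble average is the plain mean over
#' states -- the states are themselves draws from the mixture, so equal
#' weights are the discretized integral against it.  With `"density"` each
#' observable is instead averaged with weights proportional to the mixture
#' density at that state's angle, which double-counts the density and tilts
#' averages toward mode centers.  The returned ensemble carries a uniform
#' sampling prior.
#'
#' @param n_states number of conformational states (>= 2).
#' @param n_obs number of observables (>= 3).
#' @param truth the true [karplus_model()].
#' @param spec a [mixture_spec()].
#' @param seed RNG seed.
#' @param sigma_state within-ensemble angular heterogeneity (degrees).
#' @param weighting `"density"` or `"uniform"` ensemble-average weights.
#' @return a list of class `synthetic_dataset` with elements `ensemble`,
#'   `J_true`, `J_obs`, `truth`, `weights` (n_states x n_obs), `noise_record`,
#'   `seed`.
#' @export
build_toy_dataset <- function(n_states = 100, n_obs = 60,
                              truth = karplus_model(6.51, -1.76, 1.60),
                              spec = mixture_spec(), seed = NULL,
                              sigma_state = 10,
                              weighting = c("uniform", "density")) {
  stopifnot(n_states >= 2, n_obs >= 3, inherits(truth, "karplus_model"),
            sigma_state >= 0)
  weighting <- match.arg(weighting)
  if (!is.null(seed)) set.seed(seed)
  centers <- sample_phi_mixture(n_obs, spec)
  phi <- wrap_angle(matrix(rep(centers, each = n_states) +
                             stats::rnorm(n_states * n_obs, 0, sigma_state),
                           nrow = n_states, ncol = n_obs))
  if (weighting == "density") {
    w <- apply(phi, 2, function(col) {
      dens <- mixture_density(col, spec)
      dens / sum(dens)
    })
  } else {
    w <- matrix(1 / n_states, n_states, n_obs)
  }
  # generating ("true") populations are the density weights in `w`; the
  # sampling prior handed to inference is uniform -- recovering the true
  # populations is the reweighting machinery's job, not an input
  ensemble <- dihedral_ensemble(phi, NULL, truth$label)
  Jmat <- karplus_predict(phi, truth)       # vectorized over the matrix
  Jmat <- matrix(Jmat, n_states, n_obs)
  J_true <- colSums(Jmat * w)
  structure(list(ensemble = ensemble, J_true = J_true, J_obs = J_true,
                 truth = truth, weights = w,
                 noise_record = list(sigma_data = 0, shifted = integer(0),
                                     shifts = numeric(0)),
                 seed = seed),
            class = "synthetic_dataset")
}

#' Add random and systematic noise to synthetic couplings
#'
#' Adds iid Gaussian noise of SD `sigma_data` to every observable, then
#' shifts a uniformly chosen count (between 0 and `floor(frac_max * n_obs)`)
#' of observables by `+U(shift_range)` Hz to emulate systematic error.  All
#' draws are logged in `noise_record`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param sigma_data Gaussian noise SD (Hz), `>= 0`.
#' @param frac_max maximum fraction of observables shifted (default 0.2).
#' @param shift_range systematic shift range in Hz (default `c(2, 4)`).
#' @param seed optional RNG seed.
#' @return the dataset with updated `J_obs` and `noise_record`.
#' @export
add_noise <- function(dataset, sigma_data, frac_max = 0.2,
                      shift_range = c(2, 4), seed = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"), sigma_data >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(dataset$J_true)
  eps <- stats::rnorm(n, 0, sigma_data)
  n_shift_max <- floor(frac_max * n)
  n_shift <- if (n_shift_max > 0) sample.int(n_shift_max + 1L, 1L) - 1L else 0L
  shifted <- if (n_shift > 0) sort(sample.int(n, n_shift)) else integer(0)
  shifts <- stats::runif(n_shift, shift_range[1], shift_range[2])
  J_obs <- dataset$J_true + eps
  J_obs[shifted] <- J_obs[shifted] + shifts
  dataset$J_obs <- J_obs
  dataset$noise_record <- list(sigma_data = sigma_data, random = eps,
                               shifted = shifted, shifts = shifts)
  dataset
}

#' Perturb the prior ensemble angles
#'
#' Adds independent Gaussian angular noise of SD `sigma_prior` (degrees) to
#' every dihedral entry, re-wrapping into (-180, 180]; populations are left
#' unchanged.  Used to degrade the quality of the prior structural ensemble.
#'
#' @param dataset a `synthetic_dataset` (or a [dihedral_ensemble()]).
#' @param sigma_prior angular noise SD in degrees, `>= 0`.
#' @param seed optional RNG seed.
#' @return a perturbed [dihedral_ensemble()].
#' @export
perturb_prior <- function(dataset, sigma_prior, seed = NULL) {
  stopifnot(sigma_prior >= 0)
  ens <- if (inherits(dataset, "synthetic_dataset")) dataset$ensemble else dataset
  stopifnot(inherits(ens, "dihedral_ensemble"))
  if (!is.null(seed)) set.seed(seed)
  if (sigma_prior == 0) return(ens)
  noise <- matrix(stats::rnorm(length(ens$phi), 0, sigma_prior),
                  nrow = nrow(ens$phi))
  dihedral_ensemble(wrap_angle(ens$phi + noise), ens$prior_pop, ens$obs_type)
}

#' Curve-recovery RMSE of estimated Karplus coefficients
#'
#' Root-mean-square error, over the dataset's observables, between the
#' ensemble-averaged couplings under the true model and under the estimated
#' coefficients (both averaged with the dataset's generating weights).
#' `rmse_curve(dataset, dataset$truth)` is exactly 0.
#'
#' @param dataset a `synthetic_dataset`.
#' @param model estimated [karplus_model()] (or numeric `c(A, B, C)`).
#' @return RMSE in Hz.
#' @export
rmse_curve <- function(dataset, model) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (is.numeric(model))
    model <- karplus_model(model[1], model[2], model[3],
                           phi0 = dataset$truth$phi0)
  phi <- dataset$ensemble$phi
  w <- dataset$weights
  Jt <- colSums(matrix(karplus_predict(phi, dataset$truth), nrow(phi)) * w)
  Je <- colSums(matrix(karplus_predict(phi, model), nrow(phi)) * w)
  sqrt(mean((Jt - Je)^2))
}
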