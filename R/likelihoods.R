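#' Nuisance-uncertainty state
#'
#' Bundles the Bayesian uncertainty `sigma_B` (Hz) and the variance-scaling
#' parameter `phi_scale >= 1` for each observable type with the
#' per-observable finite-sampling errors, and derives the per-observable
#' total uncertainty `sigma0 = sqrt(sigma_B^2 + sem^2)`.
#'
#' @param sigma_B positive uncertainty per type (named vector, or scalar for
#'   a single type).
#' @param phi_scale variance inflator per type, `>= 1`.
#' @param sem per-observable finite-sampling errors (from
#'   [replica_average()]).
#' @param obs_type per-observable type labels (defaults to a single type).
#' @return an object of class `uncertainty_state` with per-observable
#'   `sigma0`, `sem` and per-observable expanded `sigma_B`, `phi_scale`.
#' @export
uncertainty_state <- function(sigma_B, phi_scale = 1, sem = 0,
                              obs_type = NULL) {
  if (any(sigma_B <= 0)) stop("sigma_B must be positive", call. = FALSE)
  if (any(phi_scale < 1)) stop("phi_scale must be >= 1", call. = FALSE)
  if (is.null(obs_type)) obs_type <- rep("3J", max(length(sem), 1L))
  n <- length(obs_type)
  if (length(sem) == 1L) sem <- rep(sem, n)
  stopifnot(length(sem) == n, all(sem >= 0))
  expand <- function(x) {
    if (length(x) == 1L) return(rep(x, n))
    if (is.null(names(x))) stop("per-type parameters must be named", call. = FALSE)
    unname(x[obs_type])
  }
  sB <- expand(sigma_B)
  ph <- expand(phi_scale)
  structure(list(sigma_B = sB, phi_scale = ph, sem = sem,
                 sigma0 = sqrt(sB^2 + sem^2), obs_type = obs_type),
            class = "uncertainty_state")
}

heaviside <- function(x) as.numeric(x > 0)  # H(0) = 0: gates open at the boundary

check_like_inputs <- function(pred, data, unc) {
  stopifnot(inherits(pred, "prediction_set"), inherits(unc, "uncertainty_state"))
  if (length(data) != length(pred$g) || length(unc$sigma0) != length(pred$g))
    stop("pred, data and unc must have matching lengths", call. = FALSE)
  if (any(unc$sigma0 <= 0))
    stop("sigma0 must be positive (degenerate likelihood)", call. = FALSE)
}

#' Gaussian-likelihood energy
#'
#' Negative log posterior `u` under a replica-averaged Gaussian likelihood:
#' `u = prior_energy + N * sum_j [0.5*log(2*pi*sigma0_j^2) +
#' (d_j - g_j)^2 / (2*sigma0_j^2)] + nuisance_prior_energy`.
#' The data term is multiplied by the replica count `N`.
#'
#' @param pred a `prediction_set`.
#' @param data experimental couplings (Hz), aligned with `pred$g`.
#' @param unc an [uncertainty_state()].
#' @param prior_energy replica prior energy `-sum_r log p(X_r)` in nats
#'   (default 0).
#' @param nuisance_prior_energy `-log p(sigma0)` (and `-log p(phi)`) in nats;
#'   0 means flat nuisance priors.
#' @return energy in nats.
#' @export
gaussian_energy <- function(pred, data, unc, prior_energy = 0,
                            nuisance_prior_energy = 0) {
  check_like_inputs(pred, data, unc)
  N <- pred$n_replicas
  s2 <- unc$sigma0^2
  prior_energy + nuisance_prior_energy +
    N * sum(0.5 * log(2 * pi * s2) + (data - pred$g)^2 / (2 * s2))
}

# per-observable -log of the Good-Bad two-component mixture likelihood
goodbad_nll <- function(resid, sigma0, sem, phi) {
  g1 <- 1 - heaviside(sem - sigma0)
  g2 <- 1 - heaviside(sem - phi * sigma0)
  l1 <- ifelse(g1 > 0,
               log(0.5) - 0.5 * log(2 * pi * sigma0^2) - resid^2 / (2 * sigma0^2),
               -Inf)
  l2 <- ifelse(g2 > 0,
               log(0.5) - 0.5 * log(2 * pi * phi^2 * sigma0^2) -
                 resid^2 / (2 * phi^2 * sigma0^2),
               -Inf)
  m <- pmax(l1, l2)
  -(m + log(exp(l1 - m) + exp(l2 - m)))
}

#' Good-Bad likelihood energy
#'
#' Outlier-robust energy in which each observable is modelled as an
#' equal-weight mixture of a "good" Gaussian with variance `sigma0^2` and a
#' "bad" Gaussian with variance `phi^2 sigma0^2`, the result of
#' marginalizing the unknown bad fraction uniformly and the per-observable
#' uncertainty against a two-point prior.  Heaviside gates keep each
#' component only while
#' its width exceeds the finite-sampling error.  At `phi = 1` this equals
#' [gaussian_energy()] exactly.
#'
#' @inheritParams gaussian_energy
#' @return energy in nats.
#' @export
goodbad_energy <- function(pred, data, unc, prior_energy = 0,
                           nuisance_prior_energy = 0) {
  check_like_inputs(pred, data, unc)
  if (any(unc$phi_scale < 1)) stop("phi_scale must be >= 1", call. = FALSE)
  N <- pred$n_replicas
  nll <- goodbad_nll(data - pred$g, unc$sigma0, unc$sem, unc$phi_scale)
  prior_energy + nuisance_prior_energy + N * sum(nll)
}

#' Gradient of the Good-Bad energy in the forward-model parameters
#'
#' Analytic derivative of [goodbad_energy()] with respect to the parameters
#' entering the replica-averaged predictions:
#' `du/dtheta_i = -N * sum_j (dg_j/dtheta_i) w_j (d_j - g_j) / sigma0_j^2`,
#' where `w_j` interpolates between 1 (observable in the narrow component)
#' and `1/phi^2` (observable absorbed by the wide component).  At
#' `phi = 1`, `w_j = 1` and the expression is the Gaussian gradient.
#' `sem` is held fixed, matching the prediction-set contract.
#'
#' @inheritParams gaussian_energy
#' @param fm_gradients matrix `n_obs x n_par` of `dg_j/dtheta_i`, e.g. from
#'   [karplus_gradient()] evaluated at the replica-averaged configuration,
#'   or row-averaged per-replica gradients.
#' @return numeric vector `du/dtheta` of length `n_par`.
#' @export
goodbad_grad_theta <- function(pred, data, unc, fm_gradients) {
  check_like_inputs(pred, data, unc)
  fm_gradients <- as.matrix(fm_gradients)
  if (nrow(fm_gradients) != length(pred$g))
    stop("fm_gradients must have one row per observable", call. = FALSE)
  N <- pred$n_replicas
  resid <- data - pred$g
  s0 <- unc$sigma0
  phi <- unc$phi_scale
  # mixture responsibilities of the two components (normalizers included)
  l1 <- log(0.5) - 0.5 * log(s0^2) - resid^2 / (2 * s0^2)
  l2 <- log(0.5) - 0.5 * log(phi^2 * s0^2) - resid^2 / (2 * phi^2 * s0^2)
  g1 <- 1 - heaviside(unc$sem - s0)
  g2 <- 1 - heaviside(unc$sem - phi * s0)
  m <- pmax(l1, l2)
  w1 <- g1 * exp(l1 - m)
  w2 <- g2 * exp(l2 - m)
  w <- (w1 + w2 / phi^2) / (w1 + w2)
  coef <- -N * w * resid / s0^2
  as.numeric(crossprod(fm_gradients, coef))
}

#' Multi-severity outlier specification
#'
#' Severity inflators `phi_1 = 1 < phi_2 < ... < phi_M` for the M-level
#' generalization of the Good-Bad likelihood.
#'
#' @param phi_levels strictly increasing inflators with `phi_levels[1] == 1`.
#' @export
severity_spec <- function(phi_levels) {
  if (length(phi_levels) < 1) stop("M must be >= 1", call. = FALSE)
  if (phi_levels[1] != 1) stop("phi_1 must equal 1", call. = FALSE)
  if (any(diff(phi_levels) <= 0))
    stop("phi_levels must be strictly increasing", call. = FALSE)
  structure(list(M = length(phi_levels), phi_levels = as.numeric(phi_levels)),
            class = "severity_spec")
}

#' Multi-severity Good-Bad energy
#'
#' Equal-weight (`1/M`) Heaviside-gated Gaussian scale mixture over severity
#' levels `phi_m`, the Dirichlet-marginalized M-level generalization of the
#' Good-Bad likelihood.  At `M = 1` it equals [gaussian_energy()].  Note the
#' two-component case differs from [goodbad_energy()] by the absence of the
#' `1/phi` factor on the wide component; both forms are kept as defined.
#'
#' @inheritParams gaussian_energy
#' @param spec a [severity_spec()].
#' @return energy in nats.
#' @export
multiseverity_energy <- function(pred, data, unc, spec, prior_energy = 0,
                                 nuisance_prior_energy = 0) {
  check_like_inputs(pred, data, unc)
  stopifnot(inherits(spec, "severity_spec"))
  N <- pred$n_replicas
  resid <- data - pred$g
  s0 <- unc$sigma0
  M <- spec$M
  lcomp <- vapply(spec$phi_levels, function(pm) {
    gate <- heaviside(pm * s0 - unc$sem)
    ifelse(gate > 0,
           -log(M) - 0.5 * log(2 * pi * pm^2 * s0^2) -
             resid^2 / (2 * pm^2 * s0^2),
           -Inf)
  }, numeric(length(resid)))
  lcomp <- matrix(lcomp, nrow = length(resid))
  m <- apply(lcomp, 1, max)
  if (any(!is.finite(m)))
    stop("all severity components gated out for some observable", call. = FALSE)
  nll <- -(m + log(rowSums(exp(lcomp - m))))
  prior_energy + nuisance_prior_energy + N * sum(nll)
}

#' Truncated Jeffreys prior energy for the nuisance parameters
#'
#' `-log p` for the scale parameters under priors proportional to `1/x`
#' truncated to bounded supports (uniform densities in `log x`).
#'
#' @param sigma_B,phi_scale per-type nuisance values.
#' @param sigma_bounds,phi_bounds support intervals.
#' @param include_phi whether the `phi` prior applies (Good-Bad only).
#' @return energy in nats.
#' @export
jeffreys_prior_energy <- function(sigma_B, phi_scale = NULL,
                                  sigma_bounds = c(1e-3, 10),
                                  phi_bounds = c(1, 20),
                                  include_phi = !is.null(phi_scale)) {
  if (any(sigma_B < sigma_bounds[1] | sigma_B > sigma_bounds[2]))
    return(Inf)
  u <- sum(log(sigma_B) + log(log(sigma_bounds[2] / sigma_bounds[1])))
  if (include_phi) {
    if (any(phi_scale < phi_bounds[1] | phi_scale > phi_bounds[2]))
      return(Inf)
    u <- u + sum(log(phi_scale) + log(log(phi_bounds[2] / phi_bounds[1])))
  }
  u
}
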