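#' Sampler configuration
#'
#' Settings for the composite MCMC sweep over replica states, nuisance
#' parameters and forward-model parameters.  Defaults mirror the standard
#' protocol for the toy system: 32 replicas, 10k burn-in, 50k production.
#' During burn-in, forward-model proposals are gradient-informed
#' (`theta_trial = theta_old - lrate * grad_u + eta * z`); after burn-in the
#' gradient is turned off and a plain random walk of width `step_theta` is
#' used, which keeps the production kernel symmetric.
#'
#' @param n_replicas replica count `N`.
#' @param n_burn,n_steps burn-in and production step counts.
#' @param n_anneal warm-start steps at the head of burn-in during which the
#'   outlier component is held wide open and `sigma_B` tracks a robust
#'   (median-absolute-residual) scale while the coefficients descend; the
#'   default is 60 percent of `n_burn`.  Set 0 to disable.
#' @param lrate,eta learning rate and noise scale of the burn-in proposal.
#' @param step_sigma,step_phi log-space random-walk widths for the nuisance
#'   moves.
#' @param step_theta production random-walk width for the coefficients (Hz).
#' @param step_trade width of the correlated (`sigma_B` down, `phi` up)
#'   log-space move that crosses between the sloppy-Gaussian and
#'   tight-plus-outlier basins of the Good-Bad posterior.
#' @param sem_mode normalization of the finite-sampling error: population SD
#'   across replicas divided by `sqrt(N)` (default), by `N`, or not at all.
#' @param seed RNG seed.
#' @param n_chains chains for multi-chain runs.
#' @param thin record every `thin`-th production step.
#' @param replica_moves_per_sweep replica-state move attempts per composite
#'   sweep (default: one per replica, so every replica is touched on average
#'   once per step).
#' @param sigma_bounds,phi_bounds,theta_bounds truncation bounds for the
#'   Jeffreys priors on `sigma_B` and `phi` and the flat prior box on theta.
#'   The default `sigma_B` floor of 0.1 Hz reflects the typical precision of
#'   NMR frequency measurements and keeps the narrow mixture component from
#'   collapsing onto observables the replica ensemble happens to
#'   interpolate.
#' @export
sampler_config <- function(n_replicas = 32, n_burn = 10000, n_steps = 50000,
                           n_anneal = NULL,
                           lrate = 1e-4, eta = 0.02,
                           step_sigma = 0.1, step_phi = 0.1,
                           step_theta = 0.02, step_trade = 0.4,
                           sem_mode = c("sd_over_sqrt_n", "sd_over_n", "sd"),
                           seed = 1, n_chains = 1,
                           thin = 1, replica_moves_per_sweep = NULL,
                           sigma_bounds = c(0.1, 10),
                           phi_bounds = c(1, 20),
                           theta_bounds = c(-15, 15)) {
  stopifnot(n_replicas >= 1, n_burn >= 0, n_steps >= 1, thin >= 1,
            lrate >= 0, eta >= 0, step_sigma > 0, step_phi > 0,
            step_theta > 0)
  sem_mode <- match.arg(sem_mode)
  if (is.null(n_anneal)) n_anneal <- as.integer(0.6 * n_burn)
  stopifnot(n_anneal <= n_burn)
  structure(list(n_replicas = as.integer(n_replicas),
                 n_burn = as.integer(n_burn), n_steps = as.integer(n_steps),
                 n_anneal = as.integer(n_anneal),
                 lrate = lrate, eta = eta, step_sigma = step_sigma,
                 step_phi = step_phi, step_theta = step_theta,
                 step_trade = step_trade, sem_mode = sem_mode,
                 seed = as.integer(seed), n_chains = as.integer(n_chains),
                 thin = as.integer(thin),
                 replica_moves_per_sweep = replica_moves_per_sweep,
                 sigma_bounds = sigma_bounds,
                 phi_bounds = phi_bounds, theta_bounds = theta_bounds),
            class = "sampler_config")
}

#' Gradient-informed forward-model proposal
#'
#' `theta_trial = theta_old - lrate * gradient + eta * z` with
#' standard-normal `z` per component.
#'
#' @param theta_old current parameters.
#' @param gradient energy gradient at `theta_old`.
#' @param lrate learning rate.
#' @param eta noise scale.
#' @export
propose_fm_params <- function(theta_old, gradient, lrate, eta) {
  stopifnot(length(theta_old) == length(gradient))
  theta_old - lrate * gradient + eta * stats::rnorm(length(theta_old))
}

#' Metropolis-Hastings acceptance
#'
#' Accepts with probability `min(1, exp(-(u_new - u_old)))`.  A
#' non-finite candidate energy is rejected (with a warning for `NaN`).
#'
#' @param u_new,u_old candidate and current energies (nats).
#' @export
mh_accept <- function(u_new, u_old) {
  if (is.nan(u_new)) {
    warning("NaN candidate energy; move rejected")
    return(FALSE)
  }
  if (!is.finite(u_old)) stop("current energy must be finite", call. = FALSE)
  du <- u_new - u_old
  du <= 0 || stats::runif(1) < exp(-du)
}

likelihood_code <- function(likelihood) {
  switch(likelihood, gaussian = 0L, good_bad = 1L, good_bad_multi = 2L,
         stop("unknown likelihood: ", likelihood, call. = FALSE))
}

phase_for_types <- function(types, phases = NULL) {
  out <- vapply(types, function(tp) {
    if (!is.null(phases) && tp %in% names(phases)) return(phases[[tp]])
    if (tp %in% names(karplus_phases)) return(karplus_phases[[tp]])
    0
  }, numeric(1))
  names(out) <- types
  out
}

expand_init <- function(x, K, types, default) {
  if (is.null(x)) x <- default
  if (is.matrix(x)) {
    stopifnot(nrow(x) == K || ncol(x) == 3)
    return(x)
  }
  if (length(x) == 3 && K == 1) return(matrix(x, 1, 3))
  if (length(x) == 1) return(matrix(x, K, 3))
  stop("cannot expand initial theta to ", K, " types", call. = FALSE)
}

#' Run one MCMC chain
#'
#' Samples the posterior over replica states, per-type nuisance parameters
#' `(sigma_B, phi)` and (optionally) per-type Karplus coefficients
#' `(A, B, C)` for ensemble-averaged coupling data.  Each step performs, in
#' order, one uniformly proposed replica-state move, a log-space `sigma_B`
#' move per type, a log-space `phi` move per type (Good-Bad only), and a
#' theta move per type.  The data likelihood can be tempered by
#' `xi` in `[0, 1]` (`xi = 0` samples the prior), which is how the
#' restraint-switching free energy is computed.
#'
#' @param ensemble a [dihedral_ensemble()].
#' @param data experimental couplings (Hz), aligned to the ensemble's
#'   observables.
#' @param config a [sampler_config()].
#' @param likelihood `"good_bad"`, `"gaussian"` or `"good_bad_multi"`.
#' @param init_theta initial coefficients: length-3 vector (single type) or
#'   `K x 3` matrix (one row per type, rows ordered like
#'   `unique(ensemble$obs_type)`).
#' @param init_sigma,init_phi initial nuisance values (scalar or per type).
#' @param xi restraint strength in `[0, 1]`.
#' @param sample_theta sample the coefficients (`FALSE` keeps them fixed, as
#'   in score evaluation at given theta).
#' @param severity_levels inflators for `"good_bad_multi"`.
#' @param phases optional named phase offsets per type (degrees); types named
#'   in [karplus_phases] default to those values, others to 0.
#' @param record_states also record the replica-state configuration at every
#'   recorded step (matrix `samples x n_replicas`).
#' @param fixed_predictions optional `n_states x n_obs` matrix of per-state
#'   predictions added to the Karplus part (used to drive the sampler with a
#'   neural-network forward model: set `init_theta = 0` and
#'   `sample_theta = FALSE`).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return an object of class `posterior_trace`: per-recorded-step energies
#'   (`u`, `u_prior`, `u_data`), coefficient, nuisance and gradient traces
#'   (columns = types), replica-state `occupancy`, acceptance counters and
#'   the configuration used.
#' @export
run_chain <- function(ensemble, data, config = sampler_config(),
                      likelihood = c("good_bad", "gaussian", "good_bad_multi"),
                      init_theta = NULL, init_sigma = 1, init_phi = 1.5,
                      xi = 1, sample_theta = TRUE, severity_levels = c(1, 2, 4),
                      phases = NULL, fixed_predictions = NULL,
                      record_states = FALSE, seed = NULL) {
  stopifnot(inherits(ensemble, "dihedral_ensemble"),
            inherits(config, "sampler_config"))
  likelihood <- match.arg(likelihood)
  if (xi < 0 || xi > 1) stop("xi must lie in [0, 1]", call. = FALSE)
  if (length(data) != ensemble$n_obs)
    stop("data length must match the number of observables", call. = FALSE)
  types <- unique(ensemble$obs_type)
  K <- length(types)
  type_idx <- match(ensemble$obs_type, types) - 1L
  ph <- phase_for_types(types, phases)
  cs <- cos(deg2rad(sweep(ensemble$phi, 2, ph[type_idx + 1L], "+")))
  j0 <- if (is.null(fixed_predictions)) {
    matrix(0, ensemble$n_states, ensemble$n_obs)
  } else {
    stopifnot(all(dim(fixed_predictions) == dim(ensemble$phi)))
    fixed_predictions
  }
  theta <- expand_init(init_theta, K, types, default = c(0, 0, 0))
  if (length(init_sigma) == 1) init_sigma <- rep(init_sigma, K)
  if (length(init_phi) == 1) init_phi <- rep(init_phi, K)
  init_sigma <- pmin(pmax(init_sigma, config$sigma_bounds[1]),
                     config$sigma_bounds[2])
  init_phi <- pmin(pmax(init_phi, config$phi_bounds[1]), config$phi_bounds[2])
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  init_states <- sample.int(ensemble$n_states, config$n_replicas,
                            replace = TRUE, prob = ensemble$prior_pop) - 1L
  cfg <- list(n_replicas = config$n_replicas, n_types = K,
              likelihood_code = likelihood_code(likelihood),
              severity_levels = severity_levels, xi = xi,
              sample_theta = sample_theta, lrate = config$lrate,
              eta = config$eta, step_sigma = config$step_sigma,
              step_phi = config$step_phi, step_theta = config$step_theta,
              step_trade = config$step_trade,
              sem_mode = match(config$sem_mode,
                               c("sd_over_sqrt_n", "sd_over_n", "sd")) - 1L,
              sigma_bounds = config$sigma_bounds,
              phi_bounds = config$phi_bounds,
              theta_bounds = config$theta_bounds,
              n_burn = config$n_burn, n_steps = config$n_steps,
              n_anneal = config$n_anneal,
              thin = config$thin,
              replica_moves_per_sweep = as.integer(
                config$replica_moves_per_sweep %||% config$n_replicas),
              init_A = theta[, 1], init_B = theta[, 2], init_C = theta[, 3],
              init_sigma = init_sigma, init_phi = init_phi,
              init_states = init_states, record_states = record_states)
  res <- .run_chain_cpp(cs^2, cs, j0, type_idx, as.numeric(data),
                        log(pmax(ensemble$prior_pop, 1e-300)), cfg)
  res$types <- types
  res$likelihood <- likelihood
  res$xi <- xi
  res$seed <- seed
  res$config <- config
  for (nm in c("A", "B", "C", "sigma_B", "phi", "grad_A", "grad_B", "grad_C"))
    colnames(res[[nm]]) <- types
  res$occupancy <- res$occupancy / sum(res$occupancy)
  class(res) <- "posterior_trace"
  res
}

#' @export
print.posterior_trace <- function(x, ...) {
  acc <- vapply(x$acceptance, function(a) if (a[2] > 0) a[1] / a[2] else NA_real_,
                numeric(1))
  cat(sprintf("<posterior_trace> %d samples, %d type(s), likelihood = %s, xi = %g\n",
              length(x$u), length(x$types), x$likelihood, x$xi))
  cat("  acceptance:", paste(sprintf("%s %.2f", names(acc), acc), collapse = ", "),
      "\n")
  invisible(x)
}

#' Acceptance rates by move class
#' @param trace a `posterior_trace`.
#' @export
acceptance_rates <- function(trace) {
  vapply(trace$acceptance, function(a) if (a[2] > 0) a[1] / a[2] else NA_real_,
         numeric(1))
}

#' Run several independent chains
#'
#' @inheritParams run_chain
#' @param init_thetas list of initial coefficient sets, one per chain.
#' @param seeds RNG seeds, one per chain (default `config$seed + 0:(n-1)`).
#' @param ... passed on to [run_chain()].
#' @return a list of `posterior_trace` objects.
#' @export
run_chains <- function(ensemble, data, config = sampler_config(),
                       init_thetas = list(c(9, -1, 1), c(4, 0, 3), c(0, 0, 0)),
                       seeds = NULL, ...) {
  n <- length(init_thetas)
  if (is.null(seeds)) seeds <- config$seed + seq_len(n) - 1L
  lapply(seq_len(n), function(i) {
    run_chain(ensemble, data, config, init_theta = init_thetas[[i]],
              seed = seeds[i], ...)
  })
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic multi-chain convergence diagnostic comparing between-chain and
#' within-chain variances; values near 1 indicate convergence.
#'
#' @param chains a list of equal-length numeric vectors (one per chain) or a
#'   matrix with one column per chain.
#' @return the potential scale reduction factor (scalar).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(i) chains[, i])
  m <- length(chains)
  if (m < 2) stop("at least two chains are required", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length", call. = FALSE)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  if (W == 0) stop("zero within-chain variance", call. = FALSE)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

fd_bins <- function(x) {
  # Freedman-Diaconis with a floor of 30 bins
  iqr <- stats::IQR(x)
  if (iqr == 0) return(30L)
  h <- 2 * iqr / length(x)^(1 / 3)
  max(30L, ceiling(diff(range(x)) / h))
}

map_estimate <- function(x) {
  if (stats::sd(x) == 0) return(x[1])
  br <- seq(min(x), max(x), length.out = fd_bins(x) + 1L)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Marginal posterior summaries
#'
#' Mean, standard deviation and MAP (highest-density histogram bin,
#' Freedman-Diaconis bins with a floor of 30) for each sampled parameter,
#' pooling production samples when several chains are given.
#'
#' @param trace a `posterior_trace` or list of them.
#' @return a data frame with columns `parameter`, `type`, `mean`, `sd`,
#'   `map`.
#' @export
marginal_summary <- function(trace) {
  traces <- if (inherits(trace, "posterior_trace")) list(trace) else trace
  stopifnot(length(traces) >= 1,
            all(vapply(traces, inherits, logical(1), "posterior_trace")))
  if (length(traces[[1]]$u) == 0) stop("empty trace", call. = FALSE)
  types <- traces[[1]]$types
  pars <- c("A", "B", "C", "sigma_B", "phi")
  out <- do.call(rbind, lapply(pars, function(p) {
    do.call(rbind, lapply(seq_along(types), function(k) {
      x <- unlist(lapply(traces, function(tr) tr[[p]][, k]))
      data.frame(parameter = p, type = types[k], mean = mean(x),
                 sd = stats::sd(x), map = map_estimate(x),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Posterior-mean coefficients from one or more chains
#'
#' @param trace a `posterior_trace` or list of them (samples are pooled).
#' @param type observable type (default: first).
#' @return named vector `c(A, B, C)`.
#' @export
posterior_theta <- function(trace, type = NULL) {
  s <- marginal_summary(trace)
  if (is.null(type)) type <- s$type[1]
  s <- s[s$type == type, ]
  stats::setNames(s$mean[match(c("A", "B", "C"), s$parameter)],
                  c("A", "B", "C"))
}
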