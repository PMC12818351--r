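#' Restraint-strength schedule
#'
#' Ordered xi values in `[0, 1]` bridging the unrestrained (`xi = 0`) and
#' fully restrained (`xi = 1`) ensembles.
#'
#' @param n number of values (default 11), uniformly spaced, or
#' @param values explicit strictly increasing values including 0 and 1.
#' @export
xi_schedule <- function(n = 11, values = NULL) {
  v <- if (is.null(values)) seq(0, 1, length.out = n) else as.numeric(values)
  if (length(v) < 2 || v[1] != 0 || v[length(v)] != 1 || any(diff(v) <= 0))
    stop("xi values must be strictly increasing from 0 to 1", call. = FALSE)
  structure(list(xi_values = v, count = length(v)), class = "xi_schedule")
}

#' Tempered restraint energy
#'
#' `u_xi = u_prior + xi * u_data`: the data-likelihood term raised to the
#' power `xi`, so `xi = 0` is independent of the data and `xi = 1` is the
#' full energy.  Affine in `xi` for a fixed configuration.
#'
#' @param xi restraint strength in `[0, 1]`.
#' @param prior_energy prior (replica + nuisance) energy terms, nats.
#' @param data_energy data-likelihood energy terms, nats.
#' @export
restraint_energy_at_xi <- function(xi, prior_energy, data_energy) {
  if (any(xi < 0 | xi > 1)) stop("xi must lie in [0, 1]", call. = FALSE)
  prior_energy + xi * data_energy
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Multistate Bennett acceptance ratio estimator
#'
#' Damped-Newton solution of the convex MBAR objective for the free
#' energies of `K` thermodynamic states from samples collected in each
#' state, with a block-jackknife covariance of the estimates.
#'
#' @param u_kn `K x N_total` matrix: reduced energy of every sample under
#'   every state.
#' @param N_k samples contributed by each state.
#' @param tol relative convergence tolerance (default 1e-8).
#' @param maxit maximum self-consistent iterations.
#' @return list with `f_k` (free energies, `f_k[1] = 0`), `theta`
#'   (covariance matrix of the `f_k`), `n_iter`, `overlap` (K x K matrix of
#'   average sample overlaps between states).
#' @export
mbar <- function(u_kn, N_k, tol = 1e-8, maxit = 10000) {
  u_kn <- as.matrix(u_kn)
  K <- nrow(u_kn)
  stopifnot(length(N_k) == K, sum(N_k) == ncol(u_kn), K >= 2)
  sol <- mbar_solve(u_kn, N_k, numeric(K), tol, maxit)
  if (!sol$converged) {
    worst <- which.max(vapply(seq_len(K - 1), function(k)
      abs(mean(u_kn[k + 1, ] - u_kn[k, ])), numeric(1)))
    stop(sprintf("MBAR failed to converge in %d iterations (worst-overlap pair: states %d-%d)",
                 maxit, worst, worst + 1), call. = FALSE)
  }
  f <- sol$f
  W <- mbar_weights(u_kn, N_k, f)
  # block-jackknife covariance of the free energies: delete one block of
  # every state's samples at a time and re-solve (warm-started)
  B <- min(10L, min(N_k))
  theta <- matrix(0, K, K)
  if (B >= 2) {
    ends <- cumsum(N_k)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    fb <- matrix(0, B, K)
    for (b in seq_len(B)) {
      keep <- unlist(lapply(seq_len(K), function(k) {
        idx <- starts[k]:ends[k]
        blk <- ceiling(seq_along(idx) / (length(idx) / B))
        idx[blk != b]
      }))
      Nb <- vapply(seq_len(K), function(k) {
        idx <- starts[k]:ends[k]
        blk <- ceiling(seq_along(idx) / (length(idx) / B))
        sum(blk != b)
      }, numeric(1))
      sb <- mbar_solve(u_kn[, keep, drop = FALSE], Nb, f, tol, maxit)
      fb[b, ] <- sb$f
    }
    fb <- sweep(fb, 2, colMeans(fb))
    theta <- (B - 1) / B * crossprod(fb)
  }
  list(f_k = f, theta = theta, n_iter = sol$n_iter,
       overlap = crossprod(W) %*% diag(N_k, K))
}

# damped-Newton solution of the convex MBAR objective, f[1] pinned at 0
mbar_solve <- function(u_kn, N_k, f_init, tol = 1e-8, maxit = 10000) {
  K <- nrow(u_kn)
  logN <- log(N_k)
  f <- f_init - f_init[1]
  obj <- function(fv) {
    a <- logN + fv - u_kn
    mx <- apply(a, 2, max)
    sum(mx + log(colSums(exp(sweep(a, 2, mx))))) - sum(N_k * fv)
  }
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    a <- logN + f - u_kn
    mx <- apply(a, 2, max)
    logD <- mx + log(colSums(exp(sweep(a, 2, mx))))
    w <- t(exp(sweep(a, 2, logD)))            # N x K soft-max weights
    csum <- colSums(w)
    grad <- csum - N_k
    if (max(abs(grad)) < tol * max(1, max(N_k))) {
      converged <- TRUE
      break
    }
    H <- diag(csum, K) - crossprod(w)
    step <- tryCatch({
      sstep <- numeric(K)
      sstep[-1] <- solve(H[-1, -1, drop = FALSE], -grad[-1])
      sstep
    }, error = function(e) NULL)
    ok <- FALSE
    if (!is.null(step) && all(is.finite(step))) {
      o0 <- obj(f)
      lam <- 1
      for (half in 1:20) {
        fn <- f + lam * step
        fn <- fn - fn[1]
        if (obj(fn) < o0) { f <- fn; ok <- TRUE; break }
        lam <- lam / 2
      }
    }
    if (!ok) {                                # self-consistent fallback
      fnew <- vapply(seq_len(K), function(k)
        -logsumexp(-u_kn[k, ] - logD), numeric(1))
      f <- fnew - fnew[1]
    }
  }
  list(f = f, converged = converged, n_iter = it)
}

mbar_weights <- function(u_kn, N_k, f) {
  a <- log(N_k) + f - u_kn
  mx <- apply(a, 2, max)
  logD <- mx + log(colSums(exp(sweep(a, 2, mx))))
  t(exp(sweep(-u_kn, 2, logD, "-") + f))
}

# integrated autocorrelation time via the initial positive sequence
integrated_act <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(1)
  ac <- stats::acf(x, lag.max = min(n - 1, 2000), plot = FALSE)$acf[-1]
  tau <- 1
  for (r in ac) {
    if (r <= 0) break
    tau <- tau + 2 * r
  }
  max(1, tau)
}

#' Free-energy score of switching on experimental restraints
#'
#' Runs one MCMC chain per xi value at fixed forward-model parameters,
#' thins each chain by the integrated autocorrelation time of its data
#' energy, and estimates the free-energy difference between the `xi = 1`
#' and `xi = 0` ensembles with [mbar()].  The score is reported in nats,
#' together with its block-jackknife uncertainty and the
#' replica-count-reduced value `f / N_replicas` (the score is extensive in
#' the replica number).
#'
#' @inheritParams run_chain
#' @param theta fixed coefficients: length-3 vector or `K x 3` matrix.
#' @param schedule a [xi_schedule()].
#' @param config a [sampler_config()]; score runs typically use shorter
#'   chains than full posterior sampling.
#' @param return_traces also return the per-xi traces (for gradients).
#' @return an object of class `free_energy_result`: `f`, `df`, `f_reduced`,
#'   `xi_values`, `per_state_f`, `n_samples_per_state`, and optionally
#'   `traces`.
#' @export
compute_score <- function(ensemble, data, theta,
                          schedule = xi_schedule(),
                          config = sampler_config(n_burn = 1000,
                                                  n_steps = 5000),
                          likelihood = "good_bad", seed = NULL,
                          return_traces = FALSE, ...) {
  stopifnot(inherits(schedule, "xi_schedule"))
  if (is.null(seed)) seed <- config$seed
  xis <- schedule$xi_values
  traces <- lapply(seq_along(xis), function(i) {
    run_chain(ensemble, data, config, likelihood = likelihood,
              init_theta = theta, xi = xis[i], sample_theta = FALSE,
              seed = seed + 1000L * (i - 1L), ...)
  })
  up <- lapply(traces, function(tr) tr$u_prior)
  ud <- lapply(traces, function(tr) tr$u_data)
  # decorrelate each state by the integrated autocorrelation time of u_data
  keep <- lapply(seq_along(xis), function(i) {
    tau <- integrated_act(ud[[i]] * xis[i] + up[[i]])
    seq(1, length(ud[[i]]), by = max(1L, as.integer(round(tau))))
  })
  up <- unlist(lapply(seq_along(up), function(i) up[[i]][keep[[i]]]))
  ud <- unlist(lapply(seq_along(ud), function(i) ud[[i]][keep[[i]]]))
  N_k <- vapply(keep, length, integer(1))
  u_kn <- vapply(seq_along(up), function(n)
    restraint_energy_at_xi(xis, up[n], ud[n]), numeric(length(xis)))
  u_kn <- matrix(u_kn, nrow = length(xis))
  res <- mbar(u_kn, N_k)
  K <- length(xis)
  f <- res$f_k[K] - res$f_k[1]
  df <- sqrt(max(0, res$theta[K, K] + res$theta[1, 1] - 2 * res$theta[K, 1]))
  out <- structure(list(f = f, df = df,
                        f_reduced = f / config$n_replicas,
                        xi_values = xis, per_state_f = res$f_k,
                        n_samples_per_state = N_k,
                        n_replicas = config$n_replicas),
                   class = "free_energy_result")
  if (return_traces) out$traces <- traces
  out
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("<free_energy_result> f = %.4f +/- %.4f nats (reduced f/N = %.4f), %d xi states\n",
              x$f, x$df, x$f_reduced, length(x$xi_values)))
  invisible(x)
}

#' Gradient of the score in the forward-model parameters
#'
#' The derivative of the restraint-switching free energy reduces to the
#' Boltzmann average of `du/dtheta` over the fully restrained (`xi = 1`)
#' ensemble.  Accepts either a `posterior_trace` sampled at `xi = 1` with
#' fixed theta (gradients are recorded per sample) or a matrix of per-sample
#' gradients.
#'
#' @param trace a `posterior_trace` at `xi = 1`, or a matrix
#'   (samples x parameters) of `du/dtheta`.
#' @param type observable type whose parameters are wanted (default first).
#' @return named vector `c(A, B, C)` (or column means of the matrix).
#' @export
score_gradient <- function(trace, type = NULL) {
  if (is.matrix(trace)) {
    if (nrow(trace) == 0) stop("empty sample set", call. = FALSE)
    return(colMeans(trace))
  }
  stopifnot(inherits(trace, "posterior_trace"))
  if (length(trace$u) == 0) stop("empty sample set", call. = FALSE)
  k <- if (is.null(type)) 1L else match(type, trace$types)
  c(A = mean(trace$grad_A[, k]), B = mean(trace$grad_B[, k]),
    C = mean(trace$grad_C[, k]))
}

#' Space xi values equidistantly in thermodynamic length
#'
#' Estimates the thermodynamic metric along the restraint path from a pilot
#' run as the per-xi standard deviation of the data-likelihood energy,
#' integrates it by trapezoid to an arc length, and places the requested
#' number of nodes at equal arc-length increments (endpoints pinned at 0 and
#' 1).  A degenerate pilot (zero variance everywhere) yields the uniform
#' schedule with a warning.
#'
#' @inheritParams compute_score
#' @param target_count nodes in the returned schedule (default 11).
#' @param pilot_schedule coarse schedule for the pilot (default 11 uniform).
#' @param pilot_config sampler settings for the pilot (default 5k steps per
#'   state).
#' @return a [xi_schedule()].
#' @export
optimize_xi_schedule <- function(ensemble, data, theta, target_count = 11,
                                 pilot_schedule = xi_schedule(11),
                                 pilot_config = sampler_config(n_burn = 500,
                                                               n_steps = 5000),
                                 likelihood = "good_bad", seed = NULL, ...) {
  if (is.null(seed)) seed <- pilot_config$seed
  xis <- pilot_schedule$xi_values
  sds <- vapply(seq_along(xis), function(i) {
    tr <- run_chain(ensemble, data, pilot_config, likelihood = likelihood,
                    init_theta = theta, xi = xis[i], sample_theta = FALSE,
                    seed = seed + 1000L * (i - 1L), ...)
    stats::sd(tr$u_data)
  }, numeric(1))
  if (all(sds == 0)) {
    warning("degenerate pilot (zero energy variance everywhere); returning uniform schedule")
    return(xi_schedule(target_count))
  }
  # trapezoid arc length, then inverse interpolation at equal increments
  mids <- (sds[-1] + sds[-length(sds)]) / 2
  arc <- c(0, cumsum(mids * diff(xis)))
  if (arc[length(arc)] == 0) return(xi_schedule(target_count))
  targets <- seq(0, arc[length(arc)], length.out = target_count)
  nodes <- stats::approx(arc, xis, xout = targets, ties = "ordered")$y
  nodes[1] <- 0
  nodes[target_count] <- 1
  nodes <- cummax(nodes)                      # guard monotonicity
  if (any(diff(nodes) <= 0)) {
    eps <- 1e-6
    for (i in 2:target_count)
      if (nodes[i] <= nodes[i - 1]) nodes[i] <- nodes[i - 1] + eps
    nodes <- pmin(nodes, 1)
    nodes[target_count] <- 1
  }
  xi_schedule(values = nodes)
}

#' Hessian-based uncertainty of optimized parameters
#'
#' Covariance of the forward-model parameters as the inverse Hessian of the
#' score at a minimum, with the Hessian built from central finite
#' differences of the score gradient.
#'
#' @param theta_star parameter vector at (or near) the minimum.
#' @param gradient_function function `theta -> gradient vector`.
#' @param step finite-difference step per component.
#' @return covariance matrix (symmetrized).
#' @export
hessian_uncertainty <- function(theta_star, gradient_function, step = 0.05) {
  p <- length(theta_star)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    e <- numeric(p)
    e[i] <- step
    H[i, ] <- (gradient_function(theta_star + e) -
                 gradient_function(theta_star - e)) / (2 * step)
  }
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("Hessian is not positive definite; use the variance across multiple starts instead",
         call. = FALSE)
  solve(H)
}
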