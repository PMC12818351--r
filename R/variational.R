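#' Variational minimization of the restraint-switching score
#'
#' Minimizes the free-energy score over the Karplus coefficients with
#' bounded L-BFGS-B, using the score gradient (the restrained-ensemble
#' average of `du/dtheta`).  Each objective evaluation launches a fresh
#' stochastic estimate of the score over the xi schedule; within one start,
#' every evaluation reuses the same RNG seed (common random numbers) so the
#' objective seen by the line search is deterministic.  Different starts use
#' different seeds, and the spread of the converged parameters across starts
#' is an uncertainty estimate complementary to the Hessian.
#'
#' @inheritParams compute_score
#' @param init_thetas list of starting coefficient vectors.
#' @param config sampler settings per evaluation; the default uses 4
#'   replicas and 10k MC steps per objective evaluation, split over the xi
#'   schedule.
#' @param schedule a [xi_schedule()].
#' @param maxit L-BFGS-B iteration cap per round.
#' @param rounds quasi-Newton restarts per start; each round re-seeds the
#'   common-random-number stream, letting line searches stalled by one noise
#'   realization make progress on the next.
#' @param seed base seed; start `i` uses `seed + 7919 * (i - 1)`.
#' @param objective,gradient optional deterministic replacements for the
#'   stochastic score and its gradient (used to exercise the optimizer on
#'   surrogate objectives); when given, `ensemble` and `data` are ignored.
#' @return an object of class `optimization_result`: `theta_star`, `f_star`,
#'   `grad_norm`, `per_start` (data frame of converged parameters and
#'   scores), `sd_multistart`.
#' @export
minimize_score <- function(ensemble, data,
                           init_thetas = list(c(9, -1, 1), c(4, 0, 3),
                                              c(0, 0, 0)),
                           config = sampler_config(n_replicas = 4,
                                                   n_burn = 200,
                                                   n_steps = 10000),
                           schedule = xi_schedule(6),
                           likelihood = "good_bad", maxit = 60, rounds = 3,
                           seed = 1, objective = NULL, gradient = NULL, ...) {
  # per-evaluation chain length: the configured step budget split over xi states
  eval_config <- config
  eval_config$n_steps <- max(200L, as.integer(config$n_steps / schedule$count))
  starts <- lapply(seq_along(init_thetas), function(i) {
    cur <- init_thetas[[i]]
    opt <- NULL
    for (round in seq_len(rounds)) {
      round_seed <- seed + 7919L * (i - 1L) + 131L * (round - 1L)
      fn <- if (!is.null(objective)) objective else function(theta) {
        sc <- compute_score(ensemble, data, theta, schedule, eval_config,
                            likelihood = likelihood, seed = round_seed, ...)
        sc$f
      }
      gr <- if (!is.null(gradient)) gradient else function(theta) {
        tr <- run_chain(ensemble, data, eval_config, likelihood = likelihood,
                        init_theta = theta, xi = 1, sample_theta = FALSE,
                        seed = round_seed, ...)
        unname(score_gradient(tr))
      }
      res <- tryCatch(
        stats::optim(cur, fn, gr, method = "L-BFGS-B",
                     lower = config$theta_bounds[1],
                     upper = config$theta_bounds[2],
                     control = list(maxit = maxit, factr = 1e10)),
        error = function(e) NULL)
      if (!is.null(res)) {
        cur <- res$par
        opt <- list(theta = res$par, f = res$value,
                    grad = gr(res$par), convergence = res$convergence)
      }
    }
    opt
  })
  ok <- !vapply(starts, is.null, logical(1))
  if (!any(ok))
    stop("all starts failed during line search; inspect the score surface",
         call. = FALSE)
  starts <- starts[ok]
  fs <- vapply(starts, `[[`, numeric(1), "f")
  best <- which.min(fs)
  thetas <- t(vapply(starts, `[[`, numeric(3), "theta"))
  colnames(thetas) <- c("A", "B", "C")
  per_start <- data.frame(start = seq_along(starts), thetas, f = fs)
  structure(list(theta_star = stats::setNames(starts[[best]]$theta,
                                              c("A", "B", "C")),
                 f_star = fs[best],
                 grad_norm = sqrt(sum(starts[[best]]$grad^2)),
                 per_start = per_start,
                 sd_multistart = if (length(starts) >= 2)
                   multistart_uncertainty(per_start) else NULL),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result> f* = %.4f nats at A = %.3f, B = %.3f, C = %.3f (|grad| = %.3g)\n",
              x$f_star, x$theta_star[1], x$theta_star[2], x$theta_star[3],
              x$grad_norm))
  if (!is.null(x$sd_multistart))
    cat("  multi-start SD:", paste(sprintf("%.3g", x$sd_multistart),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Cross-start parameter dispersion
#'
#' Component-wise sample standard deviation of the converged parameters
#' across optimization starts.
#'
#' @param results an `optimization_result`, its `per_start` data frame, or a
#'   matrix/list of converged parameter vectors.
#' @return named vector of per-parameter SDs.
#' @export
multistart_uncertainty <- function(results) {
  thetas <- if (inherits(results, "optimization_result")) {
    as.matrix(results$per_start[, c("A", "B", "C")])
  } else if (is.data.frame(results)) {
    as.matrix(results[, c("A", "B", "C")])
  } else if (is.list(results)) {
    do.call(rbind, results)
  } else {
    as.matrix(results)
  }
  if (nrow(thetas) < 2)
    stop("at least two completed starts are required", call. = FALSE)
  apply(thetas, 2, stats::sd)
}
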