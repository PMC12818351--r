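#' Karplus forward model
#'
#' Construct a Karplus relation `J(phi) = A*cos^2(phi + phi0) + B*cos(phi +
#' phi0) + C` linking a backbone dihedral angle (degrees) to a vicinal scalar
#' coupling (Hz).  The phase offset `phi0` is fixed per coupling type; see
#' [karplus_phases] for the six standard backbone types.
#'
#' @param A,B,C Karplus coefficients (Hz).
#' @param phi0 phase offset in degrees (default 0).
#' @param label observable-type name, e.g. `"3J_HN_HA"`.
#' @return an object of class `karplus_model`.
#' @examples
#' truth <- karplus_model(6.51, -1.76, 1.60)
#' karplus_predict(c(-60, 0, 90), truth)
#' @export
karplus_model <- function(A, B, C, phi0 = 0, label = "3J") {
  for (v in c(A, B, C, phi0)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("Karplus parameters must be finite scalars", call. = FALSE)
  }
  structure(list(A = A, B = B, C = C, phi0 = phi0, label = label),
            class = "karplus_model")
}

#' @export
print.karplus_model <- function(x, ...) {
  cat(sprintf("<karplus_model %s>  J(phi) = %.4g cos^2(phi%+g) %+.4g cos(phi%+g) %+.4g\n",
              x$label, x$A, x$phi0, x$B, x$phi0, x$C))
  invisible(x)
}

#' Phase offsets for the six backbone scalar-coupling types
#'
#' Named vector of phase shifts `phi0` (degrees) entering the Karplus
#' relation for the six vicinal backbone couplings.
#' @export
karplus_phases <- c(
  "3J_C_C"   = 0,
  "3J_C_CB"  = 60,
  "3J_HA_C"  = 120,
  "3J_HN_C"  = 180,
  "3J_HN_CB" = 60,
  "3J_HN_HA" = -60
)

deg2rad <- function(x) x * pi / 180

#' Evaluate a Karplus model
#'
#' @param phi dihedral angle(s) in degrees.
#' @param model a [karplus_model()].
#' @return predicted coupling(s) in Hz.
#' @export
karplus_predict <- function(phi, model) {
  stopifnot(inherits(model, "karplus_model"))
  if (!is.numeric(phi) || any(!is.finite(phi)))
    stop("phi must be finite numeric (degrees)", call. = FALSE)
  cs <- cos(deg2rad(phi + model$phi0))
  model$A * cs^2 + model$B * cs + model$C
}

#' Gradient of a Karplus prediction in its coefficients
#'
#' Returns `(dJ/dA, dJ/dB, dJ/dC) = (cos^2(phi+phi0), cos(phi+phi0), 1)`.
#' Second derivatives in (A, B, C) are identically zero.
#'
#' @inheritParams karplus_predict
#' @return a matrix with one row per angle and columns `A`, `B`, `C`.
#' @export
karplus_gradient <- function(phi, model) {
  stopifnot(inherits(model, "karplus_model"))
  if (!is.numeric(phi) || any(!is.finite(phi)))
    stop("phi must be finite numeric (degrees)", call. = FALSE)
  cs <- cos(deg2rad(phi + model$phi0))
  cbind(A = cs^2, B = cs, C = rep(1, length(cs)))
}

#' Conformational dihedral ensemble
#'
#' A states-by-observables matrix of backbone dihedral angles with per-state
#' prior populations and per-observable coupling-type labels.
#'
#' @param phi numeric matrix (states x observables) of angles in degrees,
#'   entries in (-180, 180].
#' @param prior_pop per-state prior populations; uniform if `NULL`.  Must be
#'   nonnegative and sum to 1 (tolerance 1e-6).
#' @param obs_type per-observable type label (recycled if length 1).
#' @return an object of class `dihedral_ensemble`.
#' @export
dihedral_ensemble <- function(phi, prior_pop = NULL, obs_type = "3J") {
  phi <- as.matrix(phi)
  if (any(!is.finite(phi)))
    stop("phi matrix must be finite", call. = FALSE)
  if (any(phi <= -180 | phi > 180))
    stop("phi entries must lie in (-180, 180]", call. = FALSE)
  n_states <- nrow(phi)
  n_obs <- ncol(phi)
  if (is.null(prior_pop)) prior_pop <- rep(1 / n_states, n_states)
  if (length(prior_pop) != n_states)
    stop("prior_pop length must equal the number of states", call. = FALSE)
  if (any(prior_pop < 0) || abs(sum(prior_pop) - 1) > 1e-6)
    stop("prior_pop must be nonnegative and sum to 1", call. = FALSE)
  if (length(obs_type) == 1L) obs_type <- rep(obs_type, n_obs)
  if (length(obs_type) != n_obs)
    stop("obs_type length must equal the number of observables", call. = FALSE)
  structure(list(phi = phi, prior_pop = as.numeric(prior_pop),
                 obs_type = as.character(obs_type),
                 n_states = n_states, n_obs = n_obs),
            class = "dihedral_ensemble")
}

#' @export
print.dihedral_ensemble <- function(x, ...) {
  cat(sprintf("<dihedral_ensemble> %d states x %d observables, %d type(s)\n",
              x$n_states, x$n_obs, length(unique(x$obs_type))))
  invisible(x)
}

# Resolve a single model or named list of models to one model per observable.
models_by_obs <- function(ensemble, models) {
  if (inherits(models, "karplus_model")) {
    return(rep(list(models), ensemble$n_obs))
  }
  stopifnot(is.list(models))
  miss <- setdiff(unique(ensemble$obs_type), names(models))
  if (length(miss))
    stop("no model supplied for type(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lapply(ensemble$obs_type, function(tp) models[[tp]])
}

#' Replica-averaged predictions with finite-sampling error
#'
#' Averages per-replica Karplus predictions over `N` replicas and attaches
#' the per-observable finite-sampling error `sem = sd_pop / sqrt(N)` (the
#' population standard deviation across replicas divided by `sqrt(N)`, so the
#' error decreases as the square root of the replica count).
#'
#' @param replica_states integer state indices, one per replica (1-based).
#' @param ensemble a [dihedral_ensemble()].
#' @param models a single [karplus_model()] or a named list keyed by
#'   observable type.
#' @return a list of class `prediction_set` with `g`, `sem`, `n_replicas`.
#' @export
replica_average <- function(replica_states, ensemble, models) {
  stopifnot(inherits(ensemble, "dihedral_ensemble"))
  n <- length(replica_states)
  if (n < 1) stop("at least one replica is required", call. = FALSE)
  if (any(replica_states < 1 | replica_states > ensemble$n_states))
    stop("replica state index out of range", call. = FALSE)
  mods <- models_by_obs(ensemble, models)
  # per-replica predictions: n_replicas x n_obs
  pred <- vapply(seq_len(ensemble$n_obs), function(j) {
    karplus_predict(ensemble$phi[replica_states, j], mods[[j]])
  }, numeric(n))
  pred <- matrix(pred, nrow = n)
  g <- colMeans(pred)
  v <- colMeans(pred^2) - g^2
  v[v < 0] <- 0
  prediction_set(g, sqrt(v / n), n)
}

#' @rdname replica_average
#' @param g,sem,n_replicas components of an already computed prediction set.
#' @export
prediction_set <- function(g, sem, n_replicas) {
  stopifnot(length(g) == length(sem), all(sem >= 0), n_replicas >= 1)
  structure(list(g = as.numeric(g), sem = as.numeric(sem),
                 n_replicas = as.integer(n_replicas)),
            class = "prediction_set")
}
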