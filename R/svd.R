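#' Population-weighted design matrix for the Karplus basis
#'
#' Row `j` holds the population-weighted basis of the ensemble-averaged
#' Karplus relation for observable `j`:
#' `(sum_X p(X) cos^2(phi_jX + phi0), sum_X p(X) cos(phi_jX + phi0), 1)`.
#'
#' @param ensemble a [dihedral_ensemble()] (or an angle matrix).
#' @param populations per-state weights (must sum to 1); a matrix with one
#'   column per observable is accepted for per-observable weights.
#' @param phi0 phase offset in degrees.
#' @return an `n_obs x 3` matrix with columns `cos2`, `cos`, `one`.
#' @export
build_design_matrix <- function(ensemble, populations = NULL, phi0 = 0) {
  phi <- if (inherits(ensemble, "dihedral_ensemble")) ensemble$phi else as.matrix(ensemble)
  if (is.null(populations)) {
    populations <- if (inherits(ensemble, "dihedral_ensemble"))
      ensemble$prior_pop else rep(1 / nrow(phi), nrow(phi))
  }
  cs <- cos(deg2rad(phi + phi0))
  if (is.matrix(populations)) {
    if (!all(dim(populations) == dim(phi)))
      stop("population matrix must match the angle matrix", call. = FALSE)
    if (any(abs(colSums(populations) - 1) > 1e-6))
      stop("each population column must sum to 1", call. = FALSE)
    M <- cbind(cos2 = colSums(cs^2 * populations),
               cos = colSums(cs * populations),
               one = rep(1, ncol(phi)))
  } else {
    if (length(populations) != nrow(phi))
      stop("populations length must equal the number of states", call. = FALSE)
    if (abs(sum(populations) - 1) > 1e-6)
      stop("populations must sum to 1", call. = FALSE)
    M <- cbind(cos2 = colSums(cs^2 * populations),
               cos = colSums(cs * populations),
               one = rep(1, ncol(phi)))
  }
  M
}

#' Regularized SVD fit of Karplus coefficients
#'
#' Solves `M theta = J_exp` through the SVD pseudo-inverse
#' `theta = V (Sigma + eps I)^-1 U^T J_exp` with a small ridge `eps` added
#' to every singular value for stability.
#'
#' @param M design matrix from [build_design_matrix()].
#' @param J_exp experimental couplings (Hz), one per row of `M`.
#' @param eps regularization added to the singular values (default 1e-6).
#' @return named vector `c(A, B, C)`.
#' @export
svd_fit <- function(M, J_exp, eps = 1e-6) {
  M <- as.matrix(M)
  if (nrow(M) < 3) stop("at least 3 observations are required", call. = FALSE)
  if (length(J_exp) != nrow(M))
    stop("J_exp length must equal nrow(M)", call. = FALSE)
  sv <- svd(M)
  cond <- sv$d[1] / sv$d[length(sv$d)]
  if (!is.finite(cond) || cond > 1e8)
    warning(sprintf("design matrix is nearly rank-deficient (condition number %.3g)",
                    cond))
  theta <- sv$v %*% ((t(sv$u) %*% J_exp) / (sv$d + eps))
  stats::setNames(as.numeric(theta), c("A", "B", "C"))
}

#' Jackknife uncertainty of SVD coefficients
#'
#' Standard deviation of each coefficient over repeated refits, each
#' omitting a random fraction of the observations (`floor(holdout_frac *
#' N_d)` rows, at least 1).
#'
#' @inheritParams svd_fit
#' @param n_iter number of refits (default 1000).
#' @param holdout_frac fraction of rows omitted per refit (default 0.1).
#' @param seed RNG seed.
#' @return named vector of per-coefficient SDs.
#' @export
jackknife_uncertainty <- function(M, J_exp, n_iter = 1000,
                                  holdout_frac = 0.1, seed = NULL) {
  M <- as.matrix(M)
  n <- nrow(M)
  n_omit <- max(1L, floor(holdout_frac * n))
  if (n - n_omit < 3)
    stop("holdout leaves fewer than 3 rows", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fits <- vapply(seq_len(n_iter), function(i) {
    omit <- sample.int(n, n_omit)
    svd_fit(M[-omit, , drop = FALSE], J_exp[-omit])
  }, numeric(3))
  apply(fits, 1, stats::sd)
}

#' SVD baseline fit of a synthetic dataset
#'
#' Convenience wrapper fitting `(A, B, C)` to a `synthetic_dataset` with its
#' generating weights, plus jackknife SDs.
#'
#' @param dataset a `synthetic_dataset`.
#' @param n_iter,holdout_frac,seed passed to [jackknife_uncertainty()].
#' @return list with `theta`, `sd`, `model`.
#' @export
svd_fit_dataset <- function(dataset, n_iter = 1000, holdout_frac = 0.1,
                            seed = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  M <- build_design_matrix(dataset$ensemble, dataset$weights,
                           phi0 = dataset$truth$phi0)
  theta <- svd_fit(M, dataset$J_obs)
  sds <- jackknife_uncertainty(M, dataset$J_obs, n_iter, holdout_frac, seed)
  list(theta = theta, sd = stats::setNames(sds, c("A", "B", "C")),
       model = karplus_model(theta[1], theta[2], theta[3],
                             phi0 = dataset$truth$phi0))
}
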