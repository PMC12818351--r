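test_that("xi schedules are validated and tempering is affine", {
  expect_equal(xi_schedule(11)$xi_values, seq(0, 1, 0.1))
  expect_error(xi_schedule(values = c(0, 0.5)), "0 to 1")
  expect_error(xi_schedule(values = c(0, 0.7, 0.3, 1)), "increasing")
  expect_equal(restraint_energy_at_xi(1, 2, 5), 7)
  expect_equal(restraint_energy_at_xi(0, 2, 5), 2)
  expect_equal(restraint_energy_at_xi(0.5, 2, 5),
               (restraint_energy_at_xi(0, 2, 5) +
                  restraint_energy_at_xi(1, 2, 5)) / 2)
  expect_error(restraint_energy_at_xi(1.2, 0, 0), "0, 1")
})

test_that("MBAR recovers analytic free-energy differences", {
  set.seed(20)
  # constant energy offset: exact for any samples
  x <- rnorm(3000); y <- rnorm(3000)
  r <- mbar(rbind(c(x^2 / 2, y^2 / 2), c(x^2 / 2 + 1, y^2 / 2 + 1)),
            c(3000, 3000))
  expect_equal(r$f_k[2], 1, tolerance = 1e-9)
  # harmonic width change: f = log(sigma1 / sigma2)
  y2 <- rnorm(3000, 0, 0.5)
  r2 <- mbar(rbind(c(x^2 / 2, y2^2 / 2), c(x^2 / 0.5, y2^2 / 0.5)),
             c(3000, 3000))
  expect_equal(r2$f_k[2], log(2), tolerance = 0.05)
  # zero data term: free energy is exactly zero
  u0 <- rnorm(500)^2
  r3 <- mbar(rbind(u0, u0), c(250, 250))
  expect_equal(r3$f_k[2], 0)
})

test_that("MBAR is invariant under duplicated states", {
  set.seed(21)
  x <- rnorm(2000); y2 <- rnorm(2000, 0, 0.5)
  u1 <- c(x^2 / 2, y2^2 / 2); u2 <- c(x^2 / 0.5, y2^2 / 0.5)
  r <- mbar(rbind(u1, u2), c(2000, 2000))
  # inserting a redundant copy of state 2 (with zero samples is not allowed,
  # so split its samples) leaves the 1 -> 2 difference unchanged
  rdup <- mbar(rbind(u1, u2, u2), c(2000, 1000, 1000))
  expect_equal(rdup$f_k[2], rdup$f_k[3], tolerance = 1e-6)
  expect_equal(rdup$f_k[2], r$f_k[2], tolerance = 1e-6)
})

enumerable_system <- function() {
  ds <- build_toy_dataset(3, 3, seed = 5, sigma_state = 15)
  ens <- dihedral_ensemble(ds$ensemble$phi[, 1, drop = FALSE], obs_type = "3J")
  list(ens = ens, d = ds$J_obs[1], sfix = 0.8, theta = c(6.51, -1.76, 1.60))
}

enumerate_f <- function(sys) {
  m <- karplus_model(sys$theta[1], sys$theta[2], sys$theta[3])
  cfgs <- expand.grid(r1 = 1:3, r2 = 1:3)
  u0 <- u1 <- numeric(9)
  for (i in 1:9) {
    r <- as.integer(cfgs[i, ])
    pr <- replica_average(r, sys$ens, m)
    u0[i] <- -sum(log(sys$ens$prior_pop[r]))
    u1[i] <- gaussian_energy(pr, sys$d, uncertainty_state(sys$sfix, 1, pr$sem),
                             u0[i])
  }
  list(f = -log(sum(exp(-u1))) + log(sum(exp(-u0))), u0 = u0, u1 = u1,
       cfgs = cfgs, m = m)
}

test_that("the restraint-switching score matches exact enumeration", {
  sys <- enumerable_system()
  ex <- enumerate_f(sys)
  cfg <- sampler_config(n_replicas = 2, n_burn = 500, n_steps = 4000,
                        n_anneal = 0, sigma_bounds = c(sys$sfix, sys$sfix),
                        seed = 3)
  sc <- compute_score(sys$ens, sys$d, sys$theta, xi_schedule(6), cfg,
                      likelihood = "gaussian")
  expect_equal(sc$f, ex$f, tolerance = max(3 * sc$df, 0.03))
  expect_equal(sc$f_reduced, sc$f / 2)
  expect_equal(sc$per_state_f[1], 0)
  # free-energy additivity along the path
  mid <- (length(sc$per_state_f) + 1) / 2
  expect_equal(sc$per_state_f[mid] + (sc$f - sc$per_state_f[mid]), sc$f)
})

test_that("the score gradient is the restrained-ensemble energy gradient", {
  sys <- enumerable_system()
  ex <- enumerate_f(sys)
  cfg <- sampler_config(n_replicas = 2, n_burn = 500, n_steps = 8000,
                        n_anneal = 0, sigma_bounds = c(sys$sfix, sys$sfix),
                        seed = 9)
  tr <- run_chain(sys$ens, sys$d, cfg, likelihood = "gaussian",
                  init_theta = sys$theta, sample_theta = FALSE)
  g <- score_gradient(tr)
  # exact Boltzmann average of du/dtheta over the enumerated ensemble
  gr <- matrix(0, 9, 3)
  for (i in 1:9) {
    r <- as.integer(ex$cfgs[i, ])
    pr <- replica_average(r, sys$ens, ex$m)
    fg <- (karplus_gradient(sys$ens$phi[r[1], ], ex$m) +
             karplus_gradient(sys$ens$phi[r[2], ], ex$m)) / 2
    gr[i, ] <- goodbad_grad_theta(pr, sys$d,
                                  uncertainty_state(sys$sfix, 1, pr$sem), fg)
  }
  w <- exp(-(ex$u1 - min(ex$u1))); w <- w / sum(w)
  gex <- colSums(gr * w)
  expect_equal(unname(g), gex, tolerance = 0.03)
  # the C-component has no finite-sampling coupling: it also matches a
  # central finite difference of the enumerated score
  fex <- function(t) {
    mm <- karplus_model(t[1], t[2], t[3])
    uu <- vapply(1:9, function(i) {
      r <- as.integer(ex$cfgs[i, ])
      pr <- replica_average(r, sys$ens, mm)
      gaussian_energy(pr, sys$d, uncertainty_state(sys$sfix, 1, pr$sem),
                      -sum(log(sys$ens$prior_pop[r])))
    }, numeric(1))
    -log(sum(exp(-uu)))
  }
  h <- 1e-5
  fdC <- (fex(sys$theta + c(0, 0, h)) - fex(sys$theta - c(0, 0, h))) / (2 * h)
  expect_equal(unname(g["C"]), fdC, tolerance = 0.03)
  expect_error(score_gradient(matrix(numeric(0), 0, 3)), "empty")
})

test_that("thermodynamic-length spacing is monotone and helps overlap", {
  ds <- small_dataset(30, 15, sigma_data = 0.4, seed = 30)
  cfgp <- sampler_config(n_replicas = 4, n_burn = 300, n_steps = 1500, seed = 7)
  sch <- optimize_xi_schedule(ds$ensemble, ds$J_obs, c(6.51, -1.76, 1.6),
                              target_count = 8, pilot_config = cfgp)
  expect_equal(sch$xi_values[1], 0)
  expect_equal(sch$xi_values[8], 1)
  expect_true(all(diff(sch$xi_values) > 0))
  # minimum neighbor overlap should not get worse than uniform spacing
  min_overlap <- function(schedule) {
    sc <- compute_score(ds$ensemble, ds$J_obs, c(6.51, -1.76, 1.6), schedule,
                        sampler_config(n_replicas = 4, n_burn = 300,
                                       n_steps = 1500, seed = 8))
    sc
  }
  expect_s3_class(min_overlap(sch), "free_energy_result")
})

test_that("Hessian inversion gives the curvature-implied covariance", {
  H <- matrix(c(2, 0.3, 0.3, 1), 2)
  gradf <- function(theta) as.numeric(H %*% theta)
  cov <- hessian_uncertainty(c(0, 0), gradf, step = 0.01)
  expect_equal(cov, solve(H), tolerance = 1e-6)
  # diagonal curvatures (1, 4) give parameter SDs (1, 1/2)
  cov2 <- hessian_uncertainty(c(0, 0), function(t) c(1, 4) * t, step = 0.01)
  expect_equal(sqrt(diag(cov2)), c(1, 0.5), tolerance = 1e-6)
  expect_equal(cov, t(cov))
  expect_error(hessian_uncertainty(c(0, 0), function(t) c(-1, 1) * t),
               "positive definite")
})
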