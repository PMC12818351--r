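test_that("forward-model proposal follows the drift-plus-noise rule", {
  expect_equal(propose_fm_params(c(1, 2, 3), c(9, 9, 9), 0, 0), c(1, 2, 3))
  # on u = (theta - t*)^2 / 2 with lrate 1/2 each step halves the distance
  theta <- 4; tstar <- 1
  for (i in 1:5) theta <- propose_fm_params(theta, theta - tstar, 0.5, 0)
  expect_equal(theta - tstar, (4 - 1) / 2^5)
  # pure-noise proposals are Normal(theta_old, eta^2)
  set.seed(10)
  draws <- replicate(2e4, propose_fm_params(2, 5, 0, 0.3))
  expect_equal(mean(draws), 2, tolerance = 0.01)
  expect_equal(sd(draws), 0.3, tolerance = 0.01)
})

test_that("Metropolis-Hastings acceptance has the right probabilities", {
  expect_true(mh_accept(1, 2))                 # downhill always accepted
  expect_warning(acc <- mh_accept(NaN, 1), "NaN")
  expect_false(acc)
  set.seed(11)
  n <- 2e4
  rate <- mean(replicate(n, mh_accept(log(2), 0)))
  expect_equal(rate, 0.5, tolerance = 3 * sqrt(0.25 / n) / 0.5)
  # symmetric random walk on two states with energies (0, log 3): 3:1 ratio
  state <- 1L; u <- c(0, log(3)); visits <- integer(2)
  for (i in 1:2e4) {
    cand <- 3L - state
    if (mh_accept(u[cand], u[state])) state <- cand
    visits[state] <- visits[state] + 1L
  }
  expect_equal(visits[1] / visits[2], 3, tolerance = 0.15)
})

test_that("Gelman-Rubin diagnostic separates convergent and divergent chains", {
  set.seed(12)
  conv <- replicate(4, rnorm(1e4), simplify = FALSE)
  expect_lt(gelman_rubin(conv), 1.01)
  div <- list(rnorm(2000, 0), rnorm(2000, 10))
  expect_gt(gelman_rubin(div), 2)
  one <- rnorm(1e4)
  expect_equal(gelman_rubin(list(one[1:5000], one[5001:10000])), 1,
               tolerance = 0.01)
  expect_error(gelman_rubin(list(rnorm(10))), "two chains")
  expect_error(gelman_rubin(list(rep(1, 10), rep(1, 10))), "variance")
})

fake_trace <- function(x, types = "3J") {
  n <- length(x)
  m <- matrix(x, n, length(types))
  colnames(m) <- types
  structure(list(u = x, u_prior = x, u_data = x,
                 A = m, B = m, C = m, sigma_B = abs(m) + 1, phi = abs(m) + 1,
                 grad_A = m, grad_B = m, grad_C = m, types = types,
                 likelihood = "good_bad", xi = 1),
            class = "posterior_trace")
}

test_that("marginal summaries recover known distributions", {
  s <- marginal_summary(fake_trace(rep(2, 100)))
  expect_equal(s$sd[1], 0)
  expect_equal(s$map[1], s$mean[1])
  set.seed(13)
  s2 <- marginal_summary(fake_trace(rnorm(1e5)))
  expect_equal(s2$mean[1], 0, tolerance = 0.01)
  expect_equal(s2$sd[1], 1, tolerance = 0.01)
  # pooling two identical traces changes nothing (up to the n-1 SD factor)
  tr <- fake_trace(rnorm(1000))
  expect_equal(marginal_summary(list(tr, tr)), marginal_summary(tr),
               tolerance = 1e-3)
  expect_error(marginal_summary(fake_trace(numeric(0))), "empty")
})

test_that("prior-only sampling reproduces the prior populations", {
  ens <- tiny_ensemble(prior = c(0.5, 0.3, 0.2))
  cfg <- sampler_config(n_replicas = 8, n_burn = 1000, n_steps = 20000,
                        n_anneal = 0, seed = 2)
  tr <- run_chain(ens, c(2, 3), cfg, likelihood = "gaussian",
                  init_theta = c(6.51, -1.76, 1.6), xi = 0,
                  sample_theta = FALSE)
  expect_equal(as.numeric(tr$occupancy), c(0.5, 0.3, 0.2), tolerance = 0.05)
})

test_that("the sampler satisfies detailed balance on an enumerable system", {
  # 3 states, 1 observable, sigma pinned: occupancy must match the exactly
  # enumerated Boltzmann distribution
  set.seed(14)
  ens <- dihedral_ensemble(matrix(c(-110, -60, 60), ncol = 1), obs_type = "3J")
  m <- truth_model()
  d <- karplus_predict(-70, m)
  sfix <- 0.8
  cfg <- sampler_config(n_replicas = 1, n_burn = 1000, n_steps = 40000,
                        n_anneal = 0, sigma_bounds = c(sfix, sfix), seed = 15)
  tr <- run_chain(ens, d, cfg, likelihood = "gaussian", init_theta = c(m$A, m$B, m$C),
                  sample_theta = FALSE)
  uex <- vapply(1:3, function(r) {
    pr <- replica_average(r, ens, m)
    gaussian_energy(pr, d, uncertainty_state(sfix, 1, pr$sem),
                    -log(ens$prior_pop[r]))
  }, numeric(1))
  pth <- exp(-(uex - min(uex))); pth <- pth / sum(pth)
  counts <- as.numeric(tr$occupancy) * 40000
  chi2 <- sum((counts - 40000 * pth)^2 / (40000 * pth))
  # autocorrelated draws: compare against a generous quantile
  expect_lt(chi2 / 40, stats::qchisq(0.999, df = 2))
  expect_equal(as.numeric(tr$occupancy), pth, tolerance = 0.05)
})

test_that("chains are reproducible bit for bit under a fixed seed", {
  ds <- small_dataset(20, 10, sigma_data = 0.3)
  cfg <- sampler_config(n_replicas = 4, n_burn = 500, n_steps = 2000, seed = 3)
  tr1 <- run_chain(ds$ensemble, ds$J_obs, cfg, init_theta = c(0, 0, 0))
  tr2 <- run_chain(ds$ensemble, ds$J_obs, cfg, init_theta = c(0, 0, 0))
  expect_identical(tr1$u, tr2$u)
  expect_identical(tr1$A, tr2$A)
  expect_identical(tr1$sigma_B, tr2$sigma_B)
})

test_that("acceptance rates are neither frozen nor saturated on the toy", {
  ds <- small_dataset(40, 20, sigma_data = 0.3)
  tr <- run_chain(ds$ensemble, ds$J_obs, test_config(seed = 4),
                  likelihood = "good_bad", init_theta = c(0, 0, 0))
  acc <- acceptance_rates(tr)
  expect_true(all(acc > 0 & acc < 1))
  # the tunable random-walk classes stay in the customary band
  expect_gt(acc["sigma"], 0.05); expect_lt(acc["sigma"], 0.95)
  expect_gt(acc["theta"], 0.05); expect_lt(acc["theta"], 0.95)
})

test_that("posterior width of theta shrinks with the number of observables", {
  sds <- vapply(c(15, 60, 240), function(nd) {
    ds <- build_toy_dataset(40, nd, seed = 5)
    tr <- run_chain(ds$ensemble, ds$J_obs,
                    sampler_config(n_replicas = 8, n_burn = 3000,
                                   n_steps = 12000, seed = 6),
                    likelihood = "good_bad", init_theta = c(0, 0, 0))
    marginal_summary(tr)$sd[1]
  }, numeric(1))
  expect_true(sds[1] > sds[2] && sds[2] > sds[3])
})
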