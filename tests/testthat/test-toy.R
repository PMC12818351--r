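test_that("mixture sampling hits the specified modes and weights", {
  one <- sample_phi_mixture(4e4, mixture_spec(-60, 10, 1), seed = 50)
  expect_equal(mean(one), -60, tolerance = 3 * 10 / sqrt(4e4))
  draws <- sample_phi_mixture(1e5, seed = 51)
  frac <- tabulate(attr(draws, "component"), 3) / 1e5
  expect_equal(frac, c(0.35, 0.5, 0.15), tolerance = 0.01)
  expect_true(all(draws > -180 & draws <= 180))
  expect_identical(c(sample_phi_mixture(100, seed = 1)),
                   c(sample_phi_mixture(100, seed = 1)))
  expect_error(mixture_spec(0, -1, 1), "invalid")
})

test_that("toy datasets are consistent, convex and reproducible", {
  # zero heterogeneity: every state shares the observable's center angle
  ds0 <- build_toy_dataset(5, 10, seed = 52, sigma_state = 0)
  expect_equal(ds0$J_true,
               karplus_predict(ds0$ensemble$phi[1, ], ds0$truth))
  ds <- build_toy_dataset(20, 15, seed = 53)
  Jmat <- matrix(karplus_predict(ds$ensemble$phi, ds$truth), 20, 15)
  expect_true(all(ds$J_true >= apply(Jmat, 2, min) - 1e-12))
  expect_true(all(ds$J_true <= apply(Jmat, 2, max) + 1e-12))
  # brute-force re-summation oracle
  brute <- vapply(seq_len(15), function(j) {
    acc <- 0
    for (x in seq_len(20))
      acc <- acc + ds$weights[x, j] *
        karplus_predict(ds$ensemble$phi[x, j], ds$truth)
    acc
  }, numeric(1))
  expect_equal(ds$J_true, brute, tolerance = 1e-12)
  # density weighting tilts toward mode centers but stays convex
  dsd <- build_toy_dataset(20, 15, seed = 53, weighting = "density")
  expect_equal(colSums(dsd$weights), rep(1, 15))
  # one master seed reproduces the dataset bit for bit
  expect_identical(build_toy_dataset(20, 15, seed = 53),
                   build_toy_dataset(20, 15, seed = 53))
})

test_that("noise injection is calibrated and fully logged", {
  ds <- build_toy_dataset(10, 1e4, seed = 54)
  same <- add_noise(ds, 0, frac_max = 0)
  expect_identical(same$J_obs, ds$J_true)
  noisy <- add_noise(ds, 1.0, frac_max = 0, seed = 55)
  expect_equal(sd(noisy$J_obs - noisy$J_true), 1.0, tolerance = 0.02)
  shifted <- add_noise(build_toy_dataset(10, 60, seed = 56), 0.3, seed = 57)
  rec <- shifted$noise_record
  expect_true(all(rec$shifts >= 2 & rec$shifts <= 4))
  expect_lte(length(rec$shifted), 12)
  expect_equal(shifted$J_obs[rec$shifted],
               shifted$J_true[rec$shifted] + rec$random[rec$shifted] +
                 rec$shifts)
})

test_that("prior perturbation is calibrated, independent and wrap-safe", {
  ds <- build_toy_dataset(100, 100, seed = 58)
  expect_identical(perturb_prior(ds, 0), ds$ensemble)
  pert <- perturb_prior(ds, 3, seed = 59)
  delta <- pert$phi - ds$ensemble$phi
  delta <- (delta + 180) %% 360 - 180
  expect_equal(sqrt(mean(delta^2)), 3, tolerance = 0.05 * 3)
  expect_equal(pert$prior_pop, ds$ensemble$prior_pop)
  # displacements uncorrelated across observables (flattened halves)
  expect_lt(abs(cor(as.numeric(delta[, 1:50]), as.numeric(delta[, 51:100]))),
            0.05)
  expect_true(all(pert$phi > -180 & pert$phi <= 180))
})

test_that("the curve metric vanishes exactly at the truth", {
  ds <- build_toy_dataset(30, 20, seed = 60)
  expect_equal(rmse_curve(ds, ds$truth), 0)
  expect_gt(rmse_curve(ds, c(5, -1, 2)), 0)
})
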