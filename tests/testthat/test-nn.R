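test_that("the angle embedding is on the unit circle and periodic", {
  expect_equal(unname(embed_phi(0)), matrix(c(1, 0), 1))
  expect_equal(unname(embed_phi(90)), matrix(c(0, 1), 1), tolerance = 1e-12)
  phi <- runif(20, -180, 180)
  expect_equal(embed_phi(phi), embed_phi(phi + 360), tolerance = 1e-12)
  expect_equal(rowSums(embed_phi(phi)^2), rep(1, 20))
})

test_that("network prediction is periodic with exact weight gradients", {
  m <- nn_init(50, seed = 61)
  phi <- runif(10, -180, 180)
  expect_equal(nn_predict(phi, m), nn_predict(phi + 360, m), tolerance = 1e-10)
  # null network predicts zero
  m0 <- m
  m0$W1[] <- 0; m0$b1[] <- 0; m0$W2[] <- 0; m0$b2 <- 0
  expect_equal(nn_predict(phi, m0), rep(0, 10))
  # finite-difference check on a handful of weights
  res <- nn_predict(30, m, grad = TRUE)
  theta0 <- bicepsfm:::nn_flatten(m)
  set.seed(62)
  for (w in sample(length(theta0), 5)) {
    h <- 1e-5
    up <- theta0; up[w] <- up[w] + h
    dn <- theta0; dn[w] <- dn[w] - h
    fd <- (nn_predict(30, bicepsfm:::nn_unflatten(up, m)) -
             nn_predict(30, bicepsfm:::nn_unflatten(dn, m))) / (2 * h)
    expect_equal(res$grad[1, w], fd, tolerance = 1e-4 * max(1, abs(fd)))
  }
})

test_that("training recovers a constant forward model", {
  truth <- karplus_model(0, 0, 3.2)
  ds <- build_toy_dataset(4, 40, truth = truth, seed = 63)
  res <- train_nn(ds, epochs = 800, n_hidden = 50, n_replicas = 8, seed = 64)
  phi <- seq(-170, 170, by = 20)
  expect_equal(nn_predict(phi, res$model), rep(3.2, length(phi)),
               tolerance = 0.05)
})

test_that("the training loop and the posterior sampler agree on a linear model", {
  # same data, Karplus-form posterior sampling vs network training; both
  # should land near the generating curve
  ds <- build_toy_dataset(5, 40, seed = 65)
  tr <- run_chain(ds$ensemble, ds$J_obs,
                  sampler_config(n_replicas = 8, n_burn = 3000,
                                 n_steps = 10000, seed = 66),
                  likelihood = "good_bad", init_theta = c(0, 0, 0))
  rmse_post <- rmse_curve(ds, posterior_theta(tr))
  res <- train_nn(ds, epochs = 1000, n_hidden = 100, seed = 67)
  rmse_nn <- nn_rmse_vs_truth(res, ds)
  expect_lt(rmse_post, 0.2)
  expect_lt(rmse_nn, 0.2)
})

test_that("gradient magnitudes scale as the inverse variance", {
  # with the nuisances pinned and sigma large, du/dg carries a 1/sigma^2 factor
  pred <- prediction_set(c(3, 4), c(0, 0), 4)
  fg <- cbind(c(1, 0.5), c(0.2, 0.1), c(1, 1))
  g_small <- goodbad_grad_theta(pred, c(3.5, 4.5),
                                uncertainty_state(0.5, 1, c(0, 0)), fg)
  g_large <- goodbad_grad_theta(pred, c(3.5, 4.5),
                                uncertainty_state(5, 1, c(0, 0)), fg)
  expect_equal(g_small / g_large, rep(100, 3), tolerance = 1e-9)
})

test_that("training aborts on a divergent configuration", {
  ds <- build_toy_dataset(4, 10, seed = 68)
  ds$J_obs <- ds$J_obs * 1e300   # force an immediately non-finite loss
  expect_error(train_nn(ds, epochs = 5, n_hidden = 10, seed = 69))
})
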