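pred1 <- function(g, sem = 0, n = 1) prediction_set(g, sem, n)

test_that("Gaussian energy matches its closed form", {
  unc <- uncertainty_state(1, 1, 0)
  # d = g, sigma0 = 1, N = 1: u = log sqrt(2 pi)
  expect_equal(gaussian_energy(pred1(5), 5, unc), 0.5 * log(2 * pi))
  # unit residual adds exactly 1/2 nat
  expect_equal(gaussian_energy(pred1(5), 6, unc),
               0.5 * log(2 * pi) + 0.5)
  # the replica count multiplies the data term
  expect_equal(gaussian_energy(pred1(5, n = 4), 6, unc),
               4 * (0.5 * log(2 * pi) + 0.5))
  expect_error(gaussian_energy(pred1(5), 5, uncertainty_state(1, 1, c(0, 0))),
               "matching")
})

test_that("Good-Bad reduces to Gaussian at phi = 1 and matches the
           omega-marginalization oracle", {
  set.seed(3)
  for (i in 1:10) {
    g <- runif(4, 0, 8); d <- g + rnorm(4); sem <- runif(4, 0, 0.3)
    unc1 <- uncertainty_state(runif(1, 0.2, 2), 1, sem)
    p <- pred1(g, sem, n = 3)
    expect_equal(goodbad_energy(p, d, unc1), gaussian_energy(p, d, unc1))
  }
  # numeric-integration oracle for the mixture (sigma0 = 1, phi = 2, d = g)
  unc2 <- uncertainty_state(1, 2, 0)
  expect_equal(goodbad_energy(pred1(5), 5, unc2),
               goodbad_numeric_nll(0, 1, 2), tolerance = 1e-8)
  # and for a 2 Hz outlier
  expect_equal(goodbad_energy(pred1(5), 7, unc2),
               goodbad_numeric_nll(2, 1, 2), tolerance = 1e-8)
  expect_error(goodbad_energy(pred1(5), 5, uncertainty_state(1, 0.5, 0)))
})

test_that("Good-Bad tails grow a factor phi^2 slower than Gaussian", {
  unc <- uncertainty_state(1, 4, 0)
  uncg <- uncertainty_state(1, 1, 0)
  r <- c(10, 20, 40)
  gb <- vapply(r, function(x) goodbad_energy(pred1(0), x, unc), numeric(1))
  ga <- vapply(r, function(x) gaussian_energy(pred1(0), x, uncg), numeric(1))
  # quadratic coefficient of the Good-Bad tail is 1/(2 phi^2)
  expect_equal(diff(gb) / diff(r^2 / 2), rep(1 / 16, 2), tolerance = 1e-3)
  expect_equal(diff(ga) / diff(r^2 / 2), rep(1, 2), tolerance = 1e-12)
})

test_that("energies are permutation invariant and continuous in the nuisances", {
  set.seed(4)
  g <- runif(6); d <- g + rnorm(6, 0, 0.5); sem <- runif(6, 0, 0.2)
  p <- pred1(g, sem, n = 2)
  idx <- sample(6)
  pp <- pred1(g[idx], sem[idx], n = 2)
  u1 <- goodbad_energy(p, d, uncertainty_state(0.7, 3, sem))
  u2 <- goodbad_energy(pp, d[idx], uncertainty_state(0.7, 3, sem[idx]))
  expect_equal(u1, u2)
  # continuity: small nuisance changes move the energy smoothly
  us <- vapply(seq(0.5, 0.9, length.out = 50), function(s)
    goodbad_energy(p, d, uncertainty_state(s, 3, sem)), numeric(1))
  expect_true(max(abs(diff(us))) < 1)
  up <- vapply(seq(1, 5, length.out = 50), function(ph)
    goodbad_energy(p, d, uncertainty_state(0.7, ph, sem)), numeric(1))
  expect_true(max(abs(diff(up))) < 1)
})

test_that("closed-form Good-Bad/Gaussian gap at d = g holds on a phi grid", {
  for (phi in c(1, 1.5, 2, 5, 10)) {
    u_gb <- goodbad_energy(pred1(5), 5, uncertainty_state(1, phi, 0))
    u_ga <- gaussian_energy(pred1(5), 5, uncertainty_state(1, 1, 0))
    expect_equal(u_gb - u_ga, -log(0.5 + 0.5 / phi), tolerance = 1e-12)
  }
})

test_that("analytic theta gradient matches finite differences of the energy", {
  set.seed(5)
  ens <- tiny_ensemble()
  m <- truth_model()
  reps <- c(1, 2, 3, 2)
  pr <- replica_average(reps, ens, m)
  d <- pr$g + c(0.4, -2.5)   # one well-fit point, one outlier
  unc <- uncertainty_state(0.6, 3, pr$sem)
  fg <- Reduce(`+`, lapply(reps, function(r)
    karplus_gradient(ens$phi[r, ], m))) / length(reps)
  ana <- goodbad_grad_theta(pr, d, unc, fg)
  h <- 1e-6
  fd <- vapply(1:3, function(i) {
    par <- c(6.51, -1.76, 1.60)
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    # perturb theta through g at fixed sem (the operation's contract)
    gup <- vapply(seq_len(2), function(j)
      mean(karplus_predict(ens$phi[reps, j], karplus_model(up[1], up[2], up[3]))),
      numeric(1))
    gdn <- vapply(seq_len(2), function(j)
      mean(karplus_predict(ens$phi[reps, j], karplus_model(dn[1], dn[2], dn[3]))),
      numeric(1))
    (goodbad_energy(prediction_set(gup, pr$sem, 4), d, unc) -
       goodbad_energy(prediction_set(gdn, pr$sem, 4), d, unc)) / (2 * h)
  }, numeric(1))
  expect_equal(ana, fd, tolerance = 1e-5)
  # zero residuals give a zero gradient
  expect_equal(goodbad_grad_theta(pr, pr$g, unc, fg), c(0, 0, 0))
  # phi = 1 reduces to the Gaussian gradient closed form
  unc1 <- uncertainty_state(0.6, 1, pr$sem)
  gauss <- -4 * colSums(fg * (d - pr$g) / unc1$sigma0^2)
  expect_equal(goodbad_grad_theta(pr, d, unc1, fg), unname(gauss))
})

test_that("multi-severity energy generalizes the Gaussian", {
  # M = 1 is exactly Gaussian
  s1 <- severity_spec(1)
  set.seed(6)
  g <- runif(5); d <- g + rnorm(5, 0, 0.4)
  unc <- uncertainty_state(0.8, 1, 0.1 * runif(5), rep("3J", 5))
  p <- pred1(g, unc$sem, n = 2)
  expect_equal(multiseverity_energy(p, d, unc, s1), gaussian_energy(p, d, unc))
  # M = 3 mode value: equal 1/M weights on properly normalized densities
  s3 <- severity_spec(c(1, 2, 4))
  u <- multiseverity_energy(pred1(5), 5, uncertainty_state(1, 1, 0), s3)
  expect_equal(u, -log((1 / 3) * (1 / sqrt(2 * pi)) * (1 + 1 / 2 + 1 / 4)))
  expect_error(severity_spec(c(2, 4)), "phi_1")
  expect_error(severity_spec(c(1, 1, 2)), "increasing")
})

test_that("Jeffreys prior energy is uniform in log scale and respects bounds", {
  e1 <- jeffreys_prior_energy(0.5, 2)
  e2 <- jeffreys_prior_energy(1.0, 4)
  expect_equal(e2 - e1, log(1 / 0.5) + log(4 / 2))
  expect_equal(jeffreys_prior_energy(100, 2), Inf)
})
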