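# shared fixtures; everything is generated in code at test time

truth_model <- function() karplus_model(6.51, -1.76, 1.60)

# tiny deterministic ensemble: 3 states x 2 observables
tiny_ensemble <- function(prior = NULL) {
  phi <- matrix(c(-110, -60, 60,
                  -100, -70, 50), nrow = 3)
  dihedral_ensemble(phi, prior, "3J")
}

# small consistent dataset for sampler-level tests
small_dataset <- function(n_states = 40, n_obs = 20, sigma_data = 0,
                          seed = 7, ...) {
  ds <- build_toy_dataset(n_states, n_obs, seed = seed, ...)
  if (sigma_data > 0) ds <- add_noise(ds, sigma_data, seed = seed + 1)
  ds
}

# fast sampler settings for tests
test_config <- function(...) {
  sampler_config(n_replicas = 8, n_burn = 2000, n_steps = 8000, ...)
}

# numeric marginalization oracle for the Good-Bad likelihood of one
# observable: integrate the two-point sigma_j prior and uniform omega prior
# directly (independent of goodbad_energy's closed form)
goodbad_numeric_nll <- function(resid, sigma0, phi) {
  integrand <- function(omega)
    omega * stats::dnorm(resid, 0, phi * sigma0) +
      (1 - omega) * stats::dnorm(resid, 0, sigma0)
  -log(stats::integrate(integrand, 0, 1)$value)
}
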