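#' Periodic angle embedding
#'
#' Maps a dihedral angle (degrees) onto the unit circle,
#' `x = (cos phi, sin phi)`, so the network input is continuous across the
#' periodic boundary.
#'
#' @param phi angle(s) in degrees.
#' @return matrix with columns `cos`, `sin`.
#' @export
embed_phi <- function(phi) {
  if (any(!is.finite(phi))) stop("phi must be finite", call. = FALSE)
  r <- deg2rad(phi)
  cbind(cos = cos(r), sin = sin(r))
}

gelu <- function(x) x * stats::pnorm(x)
gelu_prime <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

#' Initialize the coupling-prediction network
#'
#' Fully connected network 2 (angle embedding) -> `n_hidden` GELU units ->
#' 1 (coupling, Hz), with LeCun-normal weight initialization
#' (`sd = 1/sqrt(fan_in)`) and zero biases.
#'
#' @param n_hidden hidden units (default 200).
#' @param seed RNG seed.
#' @return an object of class `nn_forward_model`.
#' @export
nn_init <- function(n_hidden = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(
    W1 = matrix(stats::rnorm(n_hidden * 2, 0, 1 / sqrt(2)), n_hidden, 2),
    b1 = numeric(n_hidden),
    W2 = matrix(stats::rnorm(n_hidden, 0, 1 / sqrt(n_hidden)), 1, n_hidden),
    b2 = 0,
    n_hidden = n_hidden), class = "nn_forward_model")
}

#' @export
print.nn_forward_model <- function(x, ...) {
  cat(sprintf("<nn_forward_model> 2 -> %d (GELU) -> 1, %d weights\n",
              x$n_hidden, length(nn_flatten(x))))
  invisible(x)
}

nn_flatten <- function(model)
  c(as.numeric(model$W1), model$b1, as.numeric(model$W2), model$b2)

nn_unflatten <- function(theta, model) {
  h <- model$n_hidden
  model$W1 <- matrix(theta[1:(2 * h)], h, 2)
  model$b1 <- theta[(2 * h + 1):(3 * h)]
  model$W2 <- matrix(theta[(3 * h + 1):(4 * h)], 1, h)
  model$b2 <- theta[4 * h + 1]
  model
}

nn_forward <- function(X, model) {
  Z1 <- sweep(X %*% t(model$W1), 2, model$b1, "+")
  H <- gelu(Z1)
  pred <- as.numeric(H %*% t(model$W2)) + model$b2
  list(pred = pred, Z1 = Z1, H = H, X = X)
}

#' Neural-network coupling prediction
#'
#' Forward pass of the periodic-embedding network; predictions are
#' 360-degree periodic in `phi` by construction.  With `grad = TRUE` the
#' per-input gradient of the output with respect to every weight is
#' returned (reverse mode), in the flattened order `W1, b1, W2, b2`.
#'
#' @param phi angle(s) in degrees.
#' @param model an [nn_init()] model.
#' @param grad also return weight gradients.
#' @return predictions (Hz), or a list `pred`, `grad` (inputs x weights).
#' @export
nn_predict <- function(phi, model, grad = FALSE) {
  stopifnot(inherits(model, "nn_forward_model"))
  fw <- nn_forward(embed_phi(phi), model)
  if (!grad) return(fw$pred)
  n <- length(fw$pred)
  h <- model$n_hidden
  dZ1 <- gelu_prime(fw$Z1) * matrix(model$W2, n, h, byrow = TRUE)
  gW1 <- cbind(dZ1 * fw$X[, 1], dZ1 * fw$X[, 2])   # d/dW1 (column-major h x 2)
  g <- cbind(gW1, dZ1, fw$H, 1)
  colnames(g) <- NULL
  list(pred = fw$pred, grad = g)
}

adam_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grads
  state$v <- beta2 * state$v + (1 - beta2) * grads^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- -lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Train the network with the restraint free-energy loss
#'
#' Alternates (a) short MCMC refreshes of the nuisance parameters
#' `(sigma_B, phi)` and the replica-state occupancies at fixed weights with
#' (b) Adam updates of the weights driven by the restrained-ensemble energy
#' gradient (the score-gradient contract, with `dg/dweights` from
#' backpropagation).  Between refreshes the gradient uses the posterior-mean
#' nuisances and mean replica occupancies, keeping the loss smooth for Adam
#' while the sampled `sigma_B` adaptively sharpens the likelihood
#' (an implicit regularizer).
#'
#' @param dataset a `synthetic_dataset` (states x observables angles plus
#'   observed couplings).
#' @param epochs Adam epochs (default 2000).
#' @param lr learning rate (default 1e-3).
#' @param n_hidden hidden units (default 200).
#' @param refresh_every refresh the nuisances every this many epochs.
#' @param refresh_steps MCMC steps per refresh.
#' @param n_replicas replica count during training (default 16; with very
#'   few replicas the occupancy of a five-state ensemble is so coarse that
#'   training is dominated by sampling artifacts).
#' @param likelihood `"good_bad"` (default) or `"gaussian"`.
#' @param seed RNG seed.
#' @return list of class `nn_training_result`: `model`, `loss` (per-epoch
#'   energy trace), `sigma_B`, `phi_scale`, `occupancy`.
#' @export
train_nn <- function(dataset, epochs = 2000, lr = 1e-3, n_hidden = 200,
                     refresh_every = 10, refresh_steps = 300,
                     n_replicas = 16, likelihood = "good_bad", seed = 1) {
  stopifnot(inherits(dataset, "synthetic_dataset"), epochs >= 1)
  ens <- dataset$ensemble
  d <- dataset$J_obs
  set.seed(seed)
  model <- nn_init(n_hidden)
  X <- embed_phi(as.numeric(ens$phi))           # (states*obs) x 2
  nS <- ens$n_states
  nJ <- ens$n_obs
  pflat <- function(m) nn_flatten(m)
  theta <- pflat(model)
  adam <- list(t = 0, m = numeric(length(theta)), v = numeric(length(theta)))
  wbar <- ens$prior_pop
  sigB <- 1
  phiv <- 1.5
  refresh_cfg <- sampler_config(n_replicas = n_replicas, n_burn = 200,
                                n_steps = refresh_steps, step_sigma = 0.15,
                                step_phi = 0.15,
                                thin = max(1L, as.integer(refresh_steps / 64)))
  loss <- numeric(epochs)
  O <- NULL                       # sampled-configuration occupancy matrix
  semfac <- 1 / sqrt(n_replicas)
  for (ep in seq_len(epochs)) {
    if ((ep - 1) %% refresh_every == 0) {
      fw0 <- nn_forward(X, model)
      P <- matrix(fw0$pred, nS, nJ)
      tr <- run_chain(ens, d, refresh_cfg, likelihood = likelihood,
                      init_theta = c(0, 0, 0), init_sigma = sigB,
                      init_phi = phiv, sample_theta = FALSE,
                      fixed_predictions = P, record_states = TRUE,
                      seed = sample.int(.Machine$integer.max, 1))
      sigB <- mean(tr$sigma_B[, 1])
      phiv <- mean(tr$phi[, 1])
      sig_s <- tr$sigma_B[, 1]   # per-sample nuisance draws
      phi_s <- tr$phi[, 1]
      wbar <- as.numeric(tr$occupancy)
      R <- tr$replica_states     # samples x n_replicas
      O <- matrix(0, nrow(R), nS)
      for (r in seq_len(ncol(R)))
        O[cbind(seq_len(nrow(R)), R[, r])] <- O[cbind(seq_len(nrow(R)), R[, r])] + 1
      O <- O / n_replicas
    }
    fw <- nn_forward(X, model)
    P <- matrix(fw$pred, nS, nJ)
    # restrained-ensemble average of the energy gradient over the sampled
    # replica configurations (the score-gradient contract)
    G <- O %*% P
    V <- O %*% P^2 - G^2
    V[V < 0] <- 0
    sem <- semfac * sqrt(V)
    s0sq <- sig_s^2 + sem^2              # per-sample sigma draws (recycle by row)
    p2 <- phi_s^2
    resid <- matrix(d, nrow(G), nJ, byrow = TRUE) - G
    if (likelihood == "good_bad") {
      l1 <- log(0.5) - 0.5 * log(s0sq) - resid^2 / (2 * s0sq)
      l2 <- log(0.5) - 0.5 * log(p2 * s0sq) - resid^2 / (2 * p2 * s0sq)
      mm <- pmax(l1, l2)
      w1 <- exp(l1 - mm); w2 <- exp(l2 - mm)
      wmix <- (w1 + w2 / p2) / (w1 + w2)
      nllm <- -(mm + log(w1 + w2)) + 0.5 * log(2 * pi)
    } else {
      nllm <- 0.5 * log(2 * pi * s0sq) + resid^2 / (2 * s0sq)
      wmix <- 1
    }
    loss[ep] <- n_replicas * sum(nllm) / nrow(G)
    if (!is.finite(loss[ep]))
      stop("diverging loss at epoch ", ep, "; training aborted", call. = FALSE)
    DG <- -n_replicas * wmix * resid / s0sq
    dLdP <- crossprod(O, DG) / nrow(G)        # nS x nJ
    s_out <- as.numeric(dLdP)
    # backprop
    dH <- outer(s_out, as.numeric(model$W2))
    dZ1 <- dH * gelu_prime(fw$Z1)
    gW1 <- t(dZ1) %*% X                            # h x 2
    gb1 <- colSums(dZ1)
    gW2 <- crossprod(s_out, fw$H)                  # 1 x h
    gb2 <- sum(s_out)
    grads <- c(as.numeric(gW1), gb1, as.numeric(gW2), gb2)
    adam <- adam_step(adam, grads, lr)
    theta <- theta + adam$delta
    model <- nn_unflatten(theta, model)
  }
  structure(list(model = model, loss = loss, sigma_B = sigB,
                 phi_scale = phiv, occupancy = wbar, seed = seed),
            class = "nn_training_result")
}

#' RMSE of network predictions against the true Karplus curve
#'
#' Evaluated on the training angles (all states x observables entries).
#'
#' @param result an `nn_training_result` (or `nn_forward_model`).
#' @param dataset the `synthetic_dataset` used for training.
#' @return RMSE in Hz.
#' @export
nn_rmse_vs_truth <- function(result, dataset) {
  model <- if (inherits(result, "nn_training_result")) result$model else result
  phi <- as.numeric(dataset$ensemble$phi)
  sqrt(mean((nn_predict(phi, model) - karplus_predict(phi, dataset$truth))^2))
}
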