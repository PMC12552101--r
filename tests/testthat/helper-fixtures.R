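# shared fixtures and oracles, all built in code at test time

# small random dataset with labels and an embedding
make_toy_ds <- function(n = 10, p = 5, seed = 1, with_modality = FALSE) {
  set.seed(seed)
  omics_dataset(
    S = matrix(runif(n * p, 0, 5), n, p),
    U = matrix(runif(n * p, 0, 3), n, p),
    O = if (with_modality) matrix(runif(n * 3), n, 3) else NULL,
    cell_labels = rep(c("A", "B"), length.out = n),
    embedding = matrix(rnorm(n * 2), n, 2)
  )
}

# model whose transcription rate is frozen to a constant and whose kinetic
# rates are set exactly; used to compare the Euler recursion against the
# closed-form solution of the constant-rate kinetics
make_constant_rate_state <- function(alpha, beta, gamma, p = 1L,
                                     d = 2L, H = 2L) {
  st <- init_model(model_config(latent_dim = d, hidden_dim = H, seed = 1),
                   n_genes = p, n_features_total = 2 * p)
  st$params$Wa2[] <- 0
  # softplus^{-1}(alpha) so transcription_rate() returns alpha exactly
  st$params$ba2[] <- log(expm1(alpha))
  st$params$log_beta[] <- log(beta)
  st$params$log_gamma[] <- log(gamma)
  st
}

# closed-form solution of dU/dt = a - b U, dS/dt = b U - g S with constant a
kinetics_closed_form <- function(t, a, b, g, U0, S0) {
  U <- a / b + (U0 - a / b) * exp(-b * t)
  if (abs(g - b) < 1e-12) stop("degenerate b == g not supported")
  C1 <- b * (U0 - a / b) / (g - b)
  C2 <- S0 - a / g - C1
  S <- a / g + C1 * exp(-b * t) + C2 * exp(-g * t)
  list(U = U, S = S)
}

# central finite-difference gradient of the training objective for one
# parameter entry (independent oracle for the analytic backward pass)
numeric_grad_entry <- function(params, nm, idx, X, p, d, H, t_sign, opts, E,
                               h = 1e-6) {
  f <- function(pp) velode:::velode_step(pp, X, p, d, H, t_sign, opts,
                                         sample = TRUE, want_grad = FALSE,
                                         E = E)$loss
  pp <- params; pp[[nm]][idx] <- pp[[nm]][idx] + h
  pm <- params; pm[[nm]][idx] <- pm[[nm]][idx] - h
  (f(pp) - f(pm)) / (2 * h)
}

# default pipeline used throughout the simulation benchmarks: all genes
# kept, no size-factor normalization (simulated abundances have no depth
# variation), no moment smoothing (it biases rate identification)
benchmark_preprocess <- function(ds, p = ncol(ds$S)) {
  preprocess_dataset(ds, preprocess_config(n_top_genes = p, knn_k = 1,
                                           normalize = FALSE))
}

benchmark_control <- function(epochs = 1500, seed = 0, ...) {
  train_config(epochs = epochs, seed = seed, batch_size = 64,
               early_stop_patience = 400, ...)
}

# memoized expensive fixtures shared across acceptance tests
.fixture_env <- new.env(parent = emptyenv())

acceptance_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_linear(
      simulation_config(500, 100, "linear", noise_sd = 0.1, seed = 0))
  }
  .fixture_env$sim
}

acceptance_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    sim <- acceptance_sim()
    pp <- benchmark_preprocess(sim$dataset)
    .fixture_env$pp <- pp
    .fixture_env$fit <- velode(pp, control = benchmark_control())
  }
  .fixture_env$fit
}
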