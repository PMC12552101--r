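test_that("kinetic-rate initialization follows the log-normal(0, 0.1) law", {
  st <- init_model(model_config(latent_dim = 2, hidden_dim = 2, seed = 1),
                   n_genes = 1e5, n_features_total = 2e5)
  beta <- exp(st$params$log_beta)
  expect_lt(abs(median(beta) - 1), 0.01)
  inside <- mean(beta >= exp(-1.96 * 0.1) & beta <= exp(1.96 * 0.1))
  expect_lt(abs(inside - 0.95), 0.01)
  st2 <- init_model(model_config(latent_dim = 2, hidden_dim = 2, seed = 1),
                    n_genes = 1e5, n_features_total = 2e5)
  expect_identical(st$params, st2$params)
})

test_that("encoding respects the posterior sampling switch and sigmoid range", {
  st <- init_model(model_config(latent_dim = 4, hidden_dim = 8, seed = 2),
                   n_genes = 3, n_features_total = 6)
  X <- matrix(runif(30, -10, 10), 5, 6)
  X[2, ] <- X[1, ]  # duplicate row
  enc <- encode(st, X, sample = FALSE)
  expect_identical(enc$Z, enc$mu)
  expect_true(all(enc$t > 0 & enc$t < 1))
  expect_equal(enc$mu[1, ], enc$mu[2, ])
  expect_equal(enc$log_sigma2[1, ], enc$log_sigma2[2, ])
  expect_equal(enc$t[1], enc$t[2])
  expect_error(encode(st, X[, 1:5]), class = "velode_shape_mismatch")
})

test_that("time encoder shares its first layer with the state encoder", {
  st <- init_model(model_config(latent_dim = 3, hidden_dim = 6, seed = 3),
                   n_genes = 2, n_features_total = 4)
  X <- matrix(runif(12), 3, 4)
  before <- encode(st, X)
  # perturbing the single shared layer moves both the posterior and t
  st$params$W1 <- st$params$W1 + 0.5
  after <- encode(st, X)
  expect_false(isTRUE(all.equal(before$mu, after$mu)))
  expect_false(isTRUE(all.equal(before$t, after$t)))
})

test_that("latent ODE integration is exact on degenerate drifts", {
  st <- init_model(model_config(latent_dim = 3, hidden_dim = 4, seed = 4),
                   n_genes = 2, n_features_total = 4)
  z0 <- c(1, -2, 0.5)
  times <- c(0.1, 0.3, 0.3, 0.7)
  # zero drift: trajectory is constant
  st$params$Wo2[] <- 0; st$params$bo2[] <- 0
  out <- integrate_latent(st, z0, times)
  expect_equal(out, matrix(z0, 4, 3, byrow = TRUE))
  # constant drift c: exact Euler gives z0 + c (t_k - t_0), for both solvers
  cc <- c(0.3, -1, 2)
  st$params$bo2[] <- cc
  out <- integrate_latent(st, z0, times)
  expect_equal(out, outer(times - times[1], cc) +
                 matrix(z0, 4, 3, byrow = TRUE))
  expect_equal(out[2, ], out[3, ])  # duplicate time: zero step
  st$cfg$ode_solver <- "rk4"
  expect_equal(integrate_latent(st, z0, times), out)
  expect_error(integrate_latent(st, z0, c(0.5, 0.2)),
               class = "velode_times_not_sorted")
})

test_that("euler and rk4 agree to first order on a smooth drift", {
  st <- init_model(model_config(latent_dim = 2, hidden_dim = 8, seed = 5),
                   n_genes = 2, n_features_total = 4)
  z0 <- c(0.2, -0.1)
  coarse <- seq(0, 0.5, length.out = 6)
  fine <- seq(0, 0.5, length.out = 51)
  st$cfg$ode_solver <- "rk4"
  ref <- integrate_latent(st, z0, fine)[51, ]
  st$cfg$ode_solver <- "euler"
  e_coarse <- max(abs(integrate_latent(st, z0, coarse)[6, ] - ref))
  e_fine <- max(abs(integrate_latent(st, z0, fine)[51, ] - ref))
  expect_lt(e_fine, e_coarse)  # first-order error shrinks with the step
})

test_that("one decoder serves both latent paths", {
  st <- init_model(model_config(latent_dim = 3, hidden_dim = 5, seed = 6),
                   n_genes = 2, n_features_total = 4)
  Z <- matrix(rnorm(9), 3, 3)
  expect_identical(decode(st, Z), decode(st, Z))  # deterministic
  expect_equal(dim(decode(st, Z)), c(3L, 4L))
  Z[2, ] <- Z[1, ]
  out <- decode(st, Z)
  expect_equal(out[1, ], out[2, ])
})

test_that("transcription rates are positive under the softplus head", {
  st <- init_model(model_config(latent_dim = 3, hidden_dim = 5, seed = 7),
                   n_genes = 4, n_features_total = 8)
  Zt <- matrix(rnorm(15, sd = 5), 5, 3)
  Zt[3, ] <- Zt[1, ]
  al <- transcription_rate(st, Zt)
  expect_equal(dim(al), c(5L, 4L))
  expect_true(all(al > 0))
  expect_equal(al[1, ], al[3, ])
  st$cfg$alpha_nonneg <- FALSE
  al2 <- transcription_rate(st, Zt)
  expect_false(all(al2 > 0))
})

test_that("velocities follow the kinetic equations and scale linearly in rates", {
  U <- matrix(1, 2, 2); S <- matrix(1, 2, 2)
  v <- compute_velocity(U, S, alpha = matrix(2, 2, 2),
                        beta = c(1, 1), gamma = c(1, 1))
  expect_equal(v$Vu, matrix(1, 2, 2))
  expect_equal(v$Vs, matrix(0, 2, 2))
  # steady state: alpha = beta U and beta U = gamma S
  U2 <- matrix(c(1, 2, 3, 4), 2, 2)
  beta <- c(0.5, 2); gamma <- c(1, 0.25)
  al <- velode:::rowmult(U2, beta)
  S2 <- velode:::rowmult(U2, beta / gamma)
  v2 <- compute_velocity(U2, S2, al, beta, gamma)
  expect_equal(v2$Vu, matrix(0, 2, 2))
  expect_equal(v2$Vs, matrix(0, 2, 2), tolerance = 1e-12)
  # doubling all rates doubles both velocities at fixed (U, S)
  v3 <- compute_velocity(U2, S2, 2 * al, 2 * beta, 2 * gamma)
  expect_equal(v3$Vu, 2 * v2$Vu)
  expect_equal(v3$Vs, 2 * v2$Vs)
  expect_error(compute_velocity(U, S, matrix(1, 2, 2), c(-1, 1), c(1, 1)),
               class = "velode_invalid_rates")
})

test_that("forward outputs stay finite for extreme inputs", {
  st <- init_model(model_config(latent_dim = 4, hidden_dim = 8, seed = 8),
                   n_genes = 3, n_features_total = 6)
  X <- matrix(c(0, 1e6, -1e6, runif(27)), 5, 6)
  enc <- encode(st, X)
  expect_true(all(is.finite(enc$mu)))
  expect_true(all(is.finite(enc$t)))
  expect_true(all(is.finite(decode(st, enc$Z))))
  expect_true(all(is.finite(transcription_rate(st, enc$Z))))
})
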