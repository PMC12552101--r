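test_that("linear kinetics match the closed-form solution of the rate ODE", {
  # single gene with an effectively constant transcription rate: the
  # analytic solution U(t) = a/b + (U0 - a/b) e^{-bt} is the oracle
  cfg <- simulation_config(200, 1, "linear", noise_sd = 0, seed = 13)
  sim <- simulate_linear(cfg)
  tr <- sim$truth
  # recover the gene's constant-rate window: alpha is constant where the
  # sigmoid has saturated; restrict to cells past the switch region
  a_vals <- tr$alpha_true[, 1]
  # use cells where alpha is within 1e-6 of its final plateau
  t_ord <- order(tr$t_true)
  plateau <- abs(a_vals - a_vals[t_ord[length(t_ord)]]) < 1e-6
  expect_gte(sum(plateau), 30)  # seed chosen so the plateau is broad
  tp <- tr$t_true[plateau]
  t0 <- min(tp)
  i0 <- which(plateau)[which.min(tp)]
  a <- a_vals[i0]; b <- tr$beta_true[1]
  U0 <- tr$U_true[i0, 1]
  pred <- a / b + (U0 - a / b) * exp(-b * (tp - t0))
  expect_lt(max(abs(pred - tr$U_true[plateau, 1])), 1e-4)
})

test_that("noise-free trajectories satisfy the kinetic ODE residual", {
  cfg <- simulation_config(50, 5, "linear", noise_sd = 0, seed = 3)
  set.seed(velode:::derive_seed(3, "simulate_linear"))
  p <- 5
  beta <- exp(rnorm(p, 0, 0.1)); gamma <- exp(rnorm(p, 0, 0.1))
  a <- runif(p, 1, 5); s <- runif(p, 0.1, 0.9)
  w <- runif(p, 0.02, 0.1); b <- runif(p, 0, 0.2)
  sgn <- rep(1, p); sgn[sample.int(p, 2)] <- -1
  alpha_fun <- function(t) a * velode:::sigmoid(sgn * (t - s) / w) + b
  U0 <- alpha_fun(0) / beta; S0 <- beta * U0 / gamma
  grid <- velode:::rk4_kinetics(alpha_fun, beta, gamma, U0, S0, 0, 1)
  h <- 1e-3
  n <- nrow(grid$S)
  dS <- (grid$S[3:n, ] - grid$S[1:(n - 2), ]) / (2 * h)
  rhs <- velode:::rowmult(grid$U[2:(n - 1), ], beta) -
    velode:::rowmult(grid$S[2:(n - 1), ], gamma)
  expect_lt(max(abs(dS - rhs)), 10 * h)
})

test_that("stored truth velocities recompute exactly from rates and truth expression", {
  sim <- simulate_linear(simulation_config(80, 10, "linear", seed = 5))
  tr <- sim$truth
  v <- compute_velocity(tr$U_true, tr$S_true, tr$alpha_true,
                        tr$beta_true, tr$gamma_true)
  expect_identical(v$Vu, tr$Vu_true)
  expect_identical(v$Vs, tr$Vs_true)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- simulation_config(30, 8, "linear", seed = 7)
  expect_identical(simulate_linear(cfg), simulate_linear(cfg))
  ccfg <- simulation_config(30, 8, "circular", seed = 7,
                            with_modality = TRUE)
  expect_identical(simulate_circular(ccfg), simulate_circular(ccfg))
})

test_that("circular trajectories are periodic and settle to the limit cycle", {
  cfg <- simulation_config(100, 6, "circular", noise_sd = 0, seed = 9)
  sim <- simulate_circular(cfg)
  tr <- sim$truth
  # periodicity: two cells with (nearly) identical time mod 1 have nearly
  # identical noise-free expression
  o <- order(tr$t_true)
  t1 <- tr$t_true[o[1]]; t2 <- tr$t_true[o[2]]
  skip_if(abs(t1 - t2) > 0.01, "no close pair in this draw")
  expect_lt(max(abs(tr$S_true[o[1], ] - tr$S_true[o[2], ])),
            0.05 * max(tr$S_true))
  # limit cycle: the recorded period starts and ends at (almost) the same
  # state for every gene
  set.seed(velode:::derive_seed(9, "simulate_circular"))
  p <- 6
  beta <- exp(rnorm(p, 0, 0.1)); gamma <- exp(rnorm(p, 0, 0.1))
  a <- runif(p, 1, 5); b <- runif(p, 0, 0.2)
  on <- runif(p); len <- runif(p, 0.2, 0.8)
  alpha_fun <- function(t) b + a * (velode:::frac01(t - on) < len)
  U0 <- b / beta; S0 <- beta * U0 / gamma
  burn <- velode:::rk4_kinetics(alpha_fun, beta, gamma, U0, S0, 0, 10)
  last <- nrow(burn$U)
  grid <- velode:::rk4_kinetics(alpha_fun, beta, gamma,
                                burn$U[last, ], burn$S[last, ], 0, 1)
  expect_lt(max(abs(grid$S[1, ] - grid$S[nrow(grid$S), ])), 1e-3)
})

test_that("modality features plateau at 1 inside the induction arc", {
  cfg <- simulation_config(400, 5, "circular", noise_sd = 0, seed = 11,
                           with_modality = TRUE)
  sim <- simulate_circular(cfg)
  tr <- sim$truth
  set.seed(velode:::derive_seed(11, "simulate_circular"))
  p <- 5
  rnorm(2 * p); runif(2 * p)          # consume beta, gamma, a, b draws
  on <- runif(p); len <- runif(p, 0.2, 0.8)
  lead <- 0.05
  for (g in 1:p) {
    d <- velode:::frac01(tr$t_true - (on[g] - lead))
    core <- d > 0.1 & d < len[g] - 0.1   # deep inside the shifted arc
    if (any(core)) expect_true(all(tr$O_true[core, g] > 0.99))
  }
})

test_that("binomial thinning is an identity at keep_prob 1 and unbiased otherwise", {
  ds <- make_toy_ds(500, 100, seed = 13)
  expect_equal(binomial_thinning(ds, 1, seed = 1)$S, round(ds$S))
  thin <- binomial_thinning(ds, 0.4, seed = 1)
  m0 <- mean(round(ds$S))
  se <- sqrt(sum(round(ds$S) * 0.4 * 0.6)) / length(ds$S)
  expect_lt(abs(mean(thin$S) - 0.4 * m0), 3 * se)
  expect_identical(binomial_thinning(ds, 0.4, seed = 1),
                   binomial_thinning(ds, 0.4, seed = 1))
  expect_error(binomial_thinning(ds, 0), class = "velode_config")
})

test_that("depth down-sampling hits exact per-cell totals and preserves composition", {
  ds <- make_toy_ds(20, 10, seed = 15)
  frac <- 0.6
  out <- downsample_depth(ds, frac, seed = 2)
  tot_in <- rowSums(round(ds$S)) + rowSums(round(ds$U))
  tot_out <- rowSums(out$S) + rowSums(out$U)
  expect_equal(tot_out, floor(frac * tot_in))
  expect_identical(downsample_depth(ds, 1, seed = 3)$S, round(ds$S))
  # composition preserved in expectation: chi-square GOF on one cell
  cnt <- c(50L, 30L, 20L, 10L, 40L, 25L, 15L, 5L, 60L, 45L)
  reps <- 2000L
  set.seed(1)
  draws <- matrix(0L, reps, 10)
  for (r in seq_len(reps))
    draws[r, ] <- velode:::rmvhyper(cnt, 150L)
  expected <- cnt * 150 / sum(cnt)
  chisq <- sum((colMeans(draws) * reps - expected * reps)^2 /
                 (expected * reps))
  expect_gt(pchisq(chisq, df = 9, lower.tail = FALSE), 0.01)
})

test_that("cell-type removal subsets consistently and validates labels", {
  sim <- simulate_linear(simulation_config(60, 5, "linear", seed = 17))
  ds <- sim$dataset
  k <- sum(ds$cell_labels == "stage2")
  out <- remove_cell_type(ds, "stage2")
  expect_equal(nrow(out$S), nrow(ds$S) - k)
  expect_false("stage2" %in% out$cell_labels)
  expect_equal(nrow(out$embedding), nrow(out$S))
  # removing then pooling back restores the multiset of cells
  kept <- ds$cell_ids[ds$cell_labels != "stage2"]
  removed <- ds$cell_ids[ds$cell_labels == "stage2"]
  expect_setequal(c(out$cell_ids, removed), ds$cell_ids)
  expect_identical(out$cell_ids, kept)
  expect_error(remove_cell_type(ds, "nonexistent"),
               class = "velode_label_not_found")
})
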