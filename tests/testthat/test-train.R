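small_sim <- function(seed = 21) {
  sim <- simulate_linear(simulation_config(60, 10, "linear", seed = seed))
  list(ds = benchmark_preprocess(sim$dataset), truth = sim$truth)
}

test_that("fitting is bit-identical under a fixed seed", {
  sp <- small_sim()
  ctl <- train_config(epochs = 5, seed = 3, batch_size = 32,
                      retrain_on_inconsistency = FALSE)
  f1 <- velode(sp$ds, control = ctl)
  f2 <- velode(sp$ds, control = ctl)
  expect_identical(f1$t, f2$t)
  expect_identical(f1$velocity, f2$velocity)
  expect_identical(f1$loss_history, f2$loss_history)
})

test_that("a zero-epoch fit returns the initialized model with finite losses", {
  sp <- small_sim()
  f <- velode(sp$ds, control = train_config(epochs = 0, seed = 1))
  expect_equal(f$loss_history$epoch, 0L)
  expect_true(all(is.finite(unlist(f$loss_history))))
  expect_true(all(f$t > 0 & f$t < 1))
  init <- init_model(model_config(), n_genes = 10, n_features_total = 20)
  expect_identical(f$state$params$W1, init$params$W1)
})

test_that("direction correction follows the sign of the Pearson score", {
  set.seed(5)
  n <- 20; p <- 30
  U <- matrix(runif(n * p, 0, 3), n, p)
  S <- matrix(runif(n * p, 0, 3), n, p)
  # Vs equal to U: corr(Vs, U) = 1 per cell, corr(Vs, S) ~ 0
  dc <- direction_correction(U, U, S, 0.5, 0.5)
  expect_false(dc$flip)
  expect_gt(dc$l_pearson, 0.3)
  dc2 <- direction_correction(-U, U, S, 0.5, 0.5)
  expect_true(dc2$flip)
  expect_equal(dc2$l_pearson, -dc$l_pearson)
  # flipping twice restores the original pseudotime and velocity exactly
  tt <- runif(n); V <- matrix(rnorm(n * p), n, p)
  expect_identical(1 - (1 - tt), tt)
  expect_identical(-(-V), V)
  expect_error(direction_correction(matrix(1, 2, 3), matrix(1, 2, 3),
                                    matrix(1, 2, 3)),
               class = "velode_degenerate_correlation")
})

test_that("velocity pseudotime increases along a chain of forward velocities", {
  n <- 40
  # cells along a 1-D curve embedded in two genes
  S <- cbind(seq(0, 4, length.out = n), seq(0, 2, length.out = n)^1.5)
  U <- S * 0.5
  Vs <- rbind(S[2:n, ] - S[1:(n - 1), ], S[n, ] - S[n - 1, ])
  ds <- omics_dataset(S + 1e-6, U + 1e-6)
  chk <- velocity_pseudotime_check(seq(0, 1, length.out = n),
                                   list(Vs = Vs), ds, knn_k = 5)
  expect_true(chk$consistent)
  expect_gt(chk$corr, 0.5)
  expect_gt(cor(chk$velocity_pseudotime, seq_len(n)), 0.5)
  # reversing the velocities flips the sign of the correlation
  chk2 <- velocity_pseudotime_check(seq(0, 1, length.out = n),
                                    list(Vs = -Vs), ds, knn_k = 5)
  expect_false(chk2$consistent)
  expect_lt(chk2$corr, 0)
  # zero velocities: undefined correlation treated as consistent
  expect_warning(
    chk3 <- velocity_pseudotime_check(seq(0, 1, length.out = n),
                                      list(Vs = 0 * Vs), ds, knn_k = 5),
    "degenerate")
  expect_true(chk3$consistent)
})

test_that("predict on the training data reproduces the fit outputs", {
  sp <- small_sim()
  f <- velode(sp$ds, control = train_config(epochs = 10, seed = 2,
                                            batch_size = 32))
  pr <- predict(f)
  expect_identical(pr$t, f$t)
  expect_identical(pr$velocity$Vs, f$velocity$Vs)
  expect_identical(predict(f), predict(f))   # deterministic, no sampling
  half <- velode:::subset_cells(sp$ds, 1:30)
  pr2 <- predict(f, half)
  # same encoder on a row subset; BLAS blocking may differ in the last bit
  expect_equal(pr2$t, f$t[1:30], tolerance = 1e-12)
  expect_error(predict(f, make_toy_ds(5, 3)),
               class = "velode_shape_mismatch")
})

test_that("training reports divergence with a classed error", {
  sp <- small_sim()
  ctl <- train_config(epochs = 3, seed = 1, lr = 1e6,
                      retrain_on_inconsistency = FALSE,
                      direction_correction = FALSE)
  expect_error(velode(sp$ds, control = ctl), class = "velode_training_diverged")
})

test_that("a model fitted on half the cells generalizes its pseudotime to the rest", {
  sim <- acceptance_sim()
  pp <- benchmark_preprocess(sim$dataset)
  set.seed(99)
  idx <- sort(sample(500, 250))
  rest <- setdiff(1:500, idx)
  fit <- velode(velode:::subset_cells(pp, idx),
                control = benchmark_control(epochs = 400))
  pr <- predict(fit, velode:::subset_cells(pp, rest))
  expect_gte(abs(pearson_pseudotime(pr$t, sim$truth$t_true[rest])), 0.8)
})

test_that("the training objective descends from its initialization", {
  fit <- acceptance_fit()   # memoized benchmark fit (test-acceptance.R)
  loss <- -fit$loss_history$total
  expect_gt(mean(loss[1:20]), mean(tail(loss, 20)))
  # stochastic epochs fluctuate, but almost all sit below the starting loss
  expect_gte(mean(loss < loss[1]), 0.9)
})

test_that("model fit methods print, summarize and expose coefficients", {
  sp <- small_sim()
  f <- velode(sp$ds, control = train_config(epochs = 4, seed = 6,
                                            batch_size = 32))
  expect_output(print(f), "velode fit")
  expect_output(print(summary(f)), "beta quartiles")
  cf <- coef(f)
  expect_equal(nrow(cf), 10)
  expect_true(all(cf$beta > 0) && all(cf$gamma > 0))
  expect_equal(cf$gamma_beta_ratio, cf$gamma / cf$beta)
  r <- residuals(f)
  expect_equal(dim(r), c(60L, 20L))
  expect_equal(unname(r), feature_matrix(sp$ds) - fitted(f))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(f, type = "loss"))
  expect_invisible(plot(f, type = "phase", gene = 2))
  expect_invisible(plot(f, type = "pseudotime"))
})
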