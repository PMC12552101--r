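#' Simulation configuration
#'
#' Conditions for the kinetics benchmark: per-gene splicing (beta) and
#' degradation (gamma) rates held constant over time, transcription rates
#' alpha varying along a latent developmental time on a linear or circular
#' trajectory.
#'
#' @param n_cells,n_genes dataset dimensions.
#' @param topology \code{"linear"} or \code{"circular"}.
#' @param noise_sd relative multiplicative noise level (observed value =
#'   truth * (1 + noise_sd * N(0,1)), clipped at 0). Default 0.1.
#' @param with_modality attach an accessibility-like second modality whose
#'   features track each gene's induction arc with a small lead time
#'   (circular topology only).
#' @param seed integer seed; all simulator randomness derives from it.
#' @param rate_sd log-scale standard deviation of the log-normal draws of
#'   beta and gamma (log-mean 0). Default 0.1.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(n_cells, n_genes, topology = c("linear", "circular"),
                              noise_sd = 0.1, with_modality = FALSE,
                              seed = 1L, rate_sd = 0.1) {
  topology <- match.arg(topology)
  stopifnot(n_cells >= 2, n_genes >= 1, noise_sd >= 0, rate_sd > 0)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 topology = topology, noise_sd = noise_sd,
                 with_modality = isTRUE(with_modality),
                 seed = as.integer(seed), rate_sd = rate_sd),
            class = "simulation_config")
}

new_simulation_truth <- function(t_true, alpha_true, beta_true, gamma_true,
                                 U_true, S_true, O_true = NULL) {
  Vu <- alpha_true - rowmult(U_true, beta_true)
  Vs <- rowmult(U_true, beta_true) - rowmult(S_true, gamma_true)
  structure(list(t_true = t_true, alpha_true = alpha_true,
                 beta_true = beta_true, gamma_true = gamma_true,
                 U_true = U_true, S_true = S_true,
                 Vu_true = Vu, Vs_true = Vs, O_true = O_true),
            class = "simulation_truth")
}

# 4th-order Runge-Kutta for dU/dt = alpha(t) - beta U, dS/dt = beta U - gamma S
# alpha_fun(t) returns a length-p vector; returns grid states
rk4_kinetics <- function(alpha_fun, beta, gamma, U0, S0, t0, t1, h = 1e-3) {
  nstep <- round((t1 - t0) / h)
  tgrid <- t0 + h * (0:nstep)
  p <- length(beta)
  Ug <- matrix(0, nstep + 1L, p); Sg <- matrix(0, nstep + 1L, p)
  U <- U0; S <- S0
  Ug[1L, ] <- U; Sg[1L, ] <- S
  dU <- function(t, U) alpha_fun(t) - beta * U
  dS <- function(U, S) beta * U - gamma * S
  for (k in seq_len(nstep)) {
    t <- tgrid[k]
    k1u <- dU(t, U);           k1s <- dS(U, S)
    k2u <- dU(t + h / 2, U + h / 2 * k1u); k2s <- dS(U + h / 2 * k1u, S + h / 2 * k1s)
    k3u <- dU(t + h / 2, U + h / 2 * k2u); k3s <- dS(U + h / 2 * k2u, S + h / 2 * k2s)
    k4u <- dU(t + h, U + h * k3u);         k4s <- dS(U + h * k3u, S + h * k3s)
    U <- U + h / 6 * (k1u + 2 * k2u + 2 * k3u + k4u)
    S <- S + h / 6 * (k1s + 2 * k2s + 2 * k3s + k4s)
    Ug[k + 1L, ] <- U; Sg[k + 1L, ] <- S
  }
  list(tgrid = tgrid, U = Ug, S = Sg)
}

# linear interpolation of grid states at arbitrary times within [t0, t1]
interp_grid <- function(grid, times) {
  h <- grid$tgrid[2L] - grid$tgrid[1L]
  pos <- (times - grid$tgrid[1L]) / h
  lo <- pmin(pmax(floor(pos), 0), length(grid$tgrid) - 2L)
  w <- pos - lo
  iU <- grid$U[lo + 1L, , drop = FALSE] * (1 - w) + grid$U[lo + 2L, , drop = FALSE] * w
  iS <- grid$S[lo + 1L, , drop = FALSE] * (1 - w) + grid$S[lo + 2L, , drop = FALSE] * w
  list(U = iU, S = iS)
}

apply_noise <- function(M, noise_sd) {
  if (noise_sd == 0) return(M)
  pmax(M * (1 + noise_sd * matrix(stats::rnorm(length(M)), nrow(M))), 0)
}

stage_labels <- function(t, n_stages = 4L) {
  br <- seq(0, 1, length.out = n_stages + 1L)
  sprintf("stage%d", pmin(findInterval(t, br, rightmost.closed = TRUE), n_stages))
}

pca_embedding <- function(S) {
  pcs <- stats::prcomp(log1p(S), rank. = 2L)$x
  if (ncol(pcs) < 2L)
    pcs <- cbind(pcs, matrix(0, nrow(pcs), 2L - ncol(pcs)))
  pcs[, 1:2, drop = FALSE]
}

#' Simulate a linear developmental trajectory with known kinetics
#'
#' Each gene g gets constant rates beta_g, gamma_g ~ LogNormal(0, rate_sd)
#' and a sigmoidal transcription-rate program
#' alpha_g(t) = a_g * sigmoid(+/-(t - s_g)/w_g) + b_g (a random half of the
#' genes decreasing), with amplitude a_g ~ U(1,5), switch s_g ~ U(0.1,0.9),
#' width w_g ~ U(0.02,0.1) and basal level b_g ~ U(0,0.2). The kinetic ODEs
#' are integrated with 4th-order Runge-Kutta at step 1e-3 from the
#' steady state of alpha(0), cells are placed at t_i ~ U(0,1), and
#' multiplicative noise is applied to the observed layers only; the returned
#' truth holds noise-free expression, rates and velocities.
#'
#' @param cfg a \code{\link{simulation_config}} with linear topology.
#' @return list(dataset = \code{omics_dataset}, truth = \code{simulation_truth}).
#' @export
simulate_linear <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"), cfg$topology == "linear")
  set.seed(derive_seed(cfg$seed, "simulate_linear"))
  n <- cfg$n_cells; p <- cfg$n_genes
  beta <- exp(stats::rnorm(p, 0, cfg$rate_sd))
  gamma <- exp(stats::rnorm(p, 0, cfg$rate_sd))
  a <- stats::runif(p, 1, 5)
  s <- stats::runif(p, 0.1, 0.9)
  w <- stats::runif(p, 0.02, 0.1)
  b <- stats::runif(p, 0, 0.2)
  sgn <- rep(1, p)
  sgn[sample.int(p, floor(p / 2))] <- -1
  alpha_fun <- function(t) a * sigmoid(sgn * (t - s) / w) + b
  t_true <- stats::runif(n)
  U0 <- alpha_fun(0) / beta
  S0 <- beta * U0 / gamma
  grid <- rk4_kinetics(alpha_fun, beta, gamma, U0, S0, 0, 1)
  st <- interp_grid(grid, t_true)
  alpha_true <- eval_per_cell(alpha_fun, t_true, p)
  truth <- new_simulation_truth(t_true, alpha_true, beta, gamma, st$U, st$S)
  S_obs <- apply_noise(st$S, cfg$noise_sd)
  U_obs <- apply_noise(st$U, cfg$noise_sd)
  ds <- omics_dataset(S_obs, U_obs, cell_labels = stage_labels(t_true),
                      embedding = pca_embedding(S_obs))
  list(dataset = ds, truth = truth)
}

# evaluate a per-gene function of time at every cell: n x p matrix
eval_per_cell <- function(f, times, p) {
  A <- vapply(times, f, numeric(p))
  if (p == 1L) matrix(A, ncol = 1L) else t(A)
}

# circular arc membership: position of t relative to arc start, modulo 1
arc_pos <- function(t, on) frac01(t - on)

#' Simulate a circular (state-switch) trajectory with known kinetics
#'
#' Time lives on the unit circle. Each gene has an induction arc
#' [on_g, on_g + len_g) (len_g ~ U(0.2, 0.8)) with alpha = a_g + b_g inside
#' and alpha = b_g outside. The ODEs are integrated over several full periods
#' before the recorded one so the system reaches its limit cycle. With
#' \code{with_modality}, an accessibility-like feature per gene follows a
#' smoothed indicator of the induction arc shifted 0.05 earlier (accessibility
#' preceding transcription), plus additive noise clipped at zero.
#'
#' @param cfg a \code{\link{simulation_config}} with circular topology.
#' @param burn_in_periods full periods integrated before recording (>= 3).
#' @return list(dataset, truth); \code{truth$t_true} is interpreted modulo 1.
#' @export
simulate_circular <- function(cfg, burn_in_periods = 10L) {
  stopifnot(inherits(cfg, "simulation_config"), cfg$topology == "circular",
            burn_in_periods >= 3L)
  set.seed(derive_seed(cfg$seed, "simulate_circular"))
  n <- cfg$n_cells; p <- cfg$n_genes
  beta <- exp(stats::rnorm(p, 0, cfg$rate_sd))
  gamma <- exp(stats::rnorm(p, 0, cfg$rate_sd))
  a <- stats::runif(p, 1, 5)
  b <- stats::runif(p, 0, 0.2)
  on <- stats::runif(p)
  len <- stats::runif(p, 0.2, 0.8)
  alpha_fun <- function(t) b + a * (arc_pos(t, on) < len)
  t_true <- stats::runif(n)
  U0 <- b / beta
  S0 <- beta * U0 / gamma
  # burn-in to the limit cycle, then record one period
  burn <- rk4_kinetics(alpha_fun, beta, gamma, U0, S0, 0, burn_in_periods)
  last <- nrow(burn$U)
  grid <- rk4_kinetics(alpha_fun, beta, gamma, burn$U[last, ], burn$S[last, ],
                       0, 1)
  st <- interp_grid(grid, t_true)
  alpha_true <- eval_per_cell(alpha_fun, t_true, p)
  O_true <- NULL
  O_obs <- NULL
  if (cfg$with_modality) {
    # smoothed arc indicator, shifted earlier by the lead time
    lead <- 0.05; edge <- 0.01
    O_true <- eval_per_cell(function(t) {
      d <- arc_pos(t, on - lead)
      sigmoid((d - 2 * edge) / edge) * sigmoid((len - d - 2 * edge) / edge)
    }, t_true, p)
    O_obs <- pmax(O_true + cfg$noise_sd *
                    matrix(stats::rnorm(length(O_true)), n), 0)
  }
  truth <- new_simulation_truth(t_true, alpha_true, beta, gamma,
                                st$U, st$S, O_true = O_true)
  S_obs <- apply_noise(st$S, cfg$noise_sd)
  U_obs <- apply_noise(st$U, cfg$noise_sd)
  ds <- omics_dataset(S_obs, U_obs, O = O_obs,
                      cell_labels = stage_labels(t_true),
                      embedding = pca_embedding(S_obs))
  list(dataset = ds, truth = truth)
}

integerize <- function(M) round(M)  # round-half-to-even, deterministic

#' Binomial thinning of a dataset (read-loss perturbation)
#'
#' Each integerized entry x of S and U is replaced by an independent
#' Binomial(x, keep_prob) draw, mimicking read loss in low-quality data.
#'
#' @param ds an \code{\link{omics_dataset}} with counts-like values.
#' @param keep_prob retention probability in (0, 1].
#' @param seed integer seed.
#' @return A thinned \code{\link{omics_dataset}}.
#' @export
binomial_thinning <- function(ds, keep_prob, seed = 1L) {
  stopifnot(inherits(ds, "omics_dataset"))
  if (!(keep_prob > 0 && keep_prob <= 1))
    ve_stop("config", "keep_prob must be in (0, 1], got %g", keep_prob)
  set.seed(derive_seed(seed, "binomial_thinning"))
  thin <- function(M) {
    Mi <- integerize(M)
    matrix(stats::rbinom(length(Mi), as.vector(Mi), keep_prob),
           nrow(Mi), dimnames = dimnames(Mi))
  }
  out <- ds
  out$S <- thin(ds$S)
  out$U <- thin(ds$U)
  out
}

# multivariate hypergeometric draw: sample k items without replacement from
# categories with counts cnt
rmvhyper <- function(cnt, k) {
  total <- sum(cnt)
  out <- integer(length(cnt))
  rem <- total
  for (j in seq_along(cnt)) {
    if (k <= 0L) break
    rem <- rem - cnt[j]
    out[j] <- stats::rhyper(1L, cnt[j], rem, k)
    k <- k - out[j]
  }
  out
}

#' Down-sample total counts per cell (sequencing-depth perturbation)
#'
#' Per cell, the integerized counts of S and U jointly are resampled without
#' replacement to floor(fraction x total), preserving the multivariate
#' composition (multivariate hypergeometric).
#'
#' @inheritParams binomial_thinning
#' @param fraction fraction of each cell's total counts to keep, in (0, 1].
#' @export
downsample_depth <- function(ds, fraction, seed = 1L) {
  stopifnot(inherits(ds, "omics_dataset"))
  if (!(fraction > 0 && fraction <= 1))
    ve_stop("config", "fraction must be in (0, 1], got %g", fraction)
  set.seed(derive_seed(seed, "downsample_depth"))
  Si <- integerize(ds$S); Ui <- integerize(ds$U)
  p <- ncol(Si)
  for (i in seq_len(nrow(Si))) {
    cnt <- c(Si[i, ], Ui[i, ])
    k <- floor(fraction * sum(cnt))
    drawn <- rmvhyper(as.integer(cnt), as.integer(k))
    Si[i, ] <- drawn[seq_len(p)]
    Ui[i, ] <- drawn[p + seq_len(p)]
  }
  out <- ds
  out$S <- Si
  out$U <- Ui
  out
}

#' Remove all cells carrying a label (disconnected-trajectory perturbation)
#'
#' @param ds an \code{\link{omics_dataset}} with \code{cell_labels}.
#' @param label the label whose cells are dropped.
#' @export
remove_cell_type <- function(ds, label) {
  stopifnot(inherits(ds, "omics_dataset"))
  if (is.null(ds$cell_labels))
    ve_stop("label-not-found", "dataset has no cell labels")
  if (!label %in% ds$cell_labels)
    ve_stop("label-not-found", "label '%s' not present", label)
  subset_cells(ds, ds$cell_labels != label)
}
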