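#' Model configuration
#'
#' @param latent_dim dimension d of the latent state (default 20).
#' @param hidden_dim width of every hidden layer (default 128).
#' @param alpha_nonneg pass the transcription-rate output through softplus so
#'   alpha > 0 (default); identity output available for a literal linear head.
#' @param ode_solver integrator for \code{\link{integrate_latent}}:
#'   \code{"euler"} (default, also used during fitting) or \code{"rk4"}
#'   (diagnostics).
#' @param seed integer seed for parameter initialization.
#' @return A \code{model_config} list.
#' @export
model_config <- function(latent_dim = 20, hidden_dim = 128,
                         alpha_nonneg = TRUE,
                         ode_solver = c("euler", "rk4"), seed = 1L) {
  ode_solver <- match.arg(ode_solver)
  stopifnot(latent_dim >= 2, hidden_dim >= latent_dim)
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_dim = as.integer(hidden_dim),
                 alpha_nonneg = isTRUE(alpha_nonneg),
                 ode_solver = ode_solver, seed = as.integer(seed)),
            class = "model_config")
}

#' Initialize model parameters
#'
#' Builds the state encoder fz (shared first layer + mu / log-sigma^2 heads),
#' the time encoder ft (shared first layer + scalar head through sigmoid),
#' the latent drift network fode, the decoder fd, the transcription-rate
#' network falpha, and per-gene kinetic parameters: log beta_g and
#' log gamma_g are drawn N(0, 0.1^2), i.e. beta, gamma log-normal with
#' log-mean 0 and log-sd 0.1. Deterministic under the config seed.
#'
#' @param cfg a \code{\link{model_config}}.
#' @param n_genes number of genes p.
#' @param n_features_total input width m = 2p (+ modality features).
#' @param rate_sd log-sd of the kinetic-rate initialization (default 0.1).
#' @return A \code{model_state} list with \code{$params} and dimensions.
#' @export
init_model <- function(cfg, n_genes, n_features_total, rate_sd = 0.1) {
  stopifnot(inherits(cfg, "model_config"), n_genes >= 1,
            n_features_total >= 2 * n_genes)
  set.seed(derive_seed(cfg$seed, "init_model"))
  d <- cfg$latent_dim; H <- cfg$hidden_dim
  m <- as.integer(n_features_total); p <- as.integer(n_genes)
  l1 <- init_linear(m, H)     # shared first layer of fz and ft
  lmu <- init_linear(H, d)
  lls <- init_linear(H, d)
  lt <- init_linear(H, 1L)
  lo1 <- init_linear(d, H); lo2 <- init_linear(H, d)
  ld1 <- init_linear(d, H); ld2 <- init_linear(H, m)
  la1 <- init_linear(d, H); la2 <- init_linear(H, p)
  params <- list(
    W1 = l1$W, b1 = l1$b,
    Wmu = lmu$W, bmu = lmu$b,
    Wls = lls$W, bls = lls$b,
    Wt = lt$W, bt = lt$b,
    Wo1 = lo1$W, bo1 = lo1$b, Wo2 = lo2$W, bo2 = lo2$b,
    Wd1 = ld1$W, bd1 = ld1$b, Wd2 = ld2$W, bd2 = ld2$b,
    Wa1 = la1$W, ba1 = la1$b, Wa2 = la2$W, ba2 = la2$b,
    log_beta = stats::rnorm(p, 0, rate_sd),
    log_gamma = stats::rnorm(p, 0, rate_sd)
  )
  structure(list(params = params, cfg = cfg, d = d, H = H, m = m, p = p,
                 t_sign = 1),
            class = "model_state")
}

#' Kinetic rates of a model
#' @param state a \code{model_state}.
#' @return list(beta, gamma), both positive length-p vectors.
#' @export
kinetic_rates <- function(state) {
  list(beta = exp(state$params$log_beta),
       gamma = exp(state$params$log_gamma))
}

#' Encode cells into the latent posterior and pseudotime
#'
#' (mu, log sigma^2) = fz(X); Z = mu + sigma * E with E ~ N(0, I) when
#' \code{sample} is on, Z = mu otherwise; t = sigmoid(ft(X)) in (0, 1).
#' ft shares its first layer with fz.
#'
#' @param state a \code{model_state}.
#' @param X n x m input matrix (columns: spliced, unspliced, modality).
#' @param sample draw Z from the posterior (training) or use the mean (eval).
#' @return list(mu, log_sigma2, Z, t, order) where \code{order} sorts t
#'   ascending (ties by original index).
#' @export
encode <- function(state, X, sample = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != state$m)
    ve_stop("shape-mismatch", "X has %d features, model expects %d",
            ncol(X), state$m)
  pr <- state$params
  H1 <- dense_forward(X, pr$W1, pr$b1)
  mu <- addb(H1 %*% pr$Wmu, pr$bmu)
  ls <- clamp_ls(addb(H1 %*% pr$Wls, pr$bls))
  Z <- if (sample)
    mu + exp(ls / 2) * matrix(stats::rnorm(length(mu)), nrow(mu))
  else mu
  traw <- drop(H1 %*% pr$Wt + pr$bt[1L]) * state$t_sign
  tt <- sigmoid(traw)
  list(mu = mu, log_sigma2 = ls, Z = Z, t = tt,
       order = order(tt, seq_along(tt)))
}

fode_eval <- function(params, z) {
  g <- elu(drop(z %*% params$Wo1) + params$bo1)
  drop(g %*% params$Wo2) + params$bo2
}

#' Integrate the latent ODE dZt/dt = fode(Zt)
#'
#' Explicit Euler by default (each step assumes the drift stable over the
#' short interval between adjacent pseudotime points); classical RK4
#' available via the model config.
#'
#' @param state a \code{model_state}.
#' @param Zt0 latent state (length d) at \code{times[1]}.
#' @param times non-decreasing pseudotime sequence.
#' @return length(times) x d matrix; first row equals \code{Zt0} exactly.
#' @export
integrate_latent <- function(state, Zt0, times) {
  if (is.unsorted(times)) ve_stop("times-not-sorted", "times must be ascending")
  d <- state$d
  stopifnot(length(Zt0) == d)
  n <- length(times)
  out <- matrix(0, n, d)
  out[1L, ] <- Zt0
  pr <- state$params
  z <- Zt0
  for (k in seq_len(n - 1L)) {
    h <- times[k + 1L] - times[k]
    if (state$cfg$ode_solver == "rk4") {
      k1 <- fode_eval(pr, z)
      k2 <- fode_eval(pr, z + h / 2 * k1)
      k3 <- fode_eval(pr, z + h / 2 * k2)
      k4 <- fode_eval(pr, z + h * k3)
      z <- z + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    } else {
      z <- z + fode_eval(pr, z) * h
    }
    out[k + 1L, ] <- z
  }
  out
}

#' Decode latent states back to feature space
#'
#' The same decoder fd serves both the posterior sample Z and the
#' ODE-evolved Zt.
#' @param state a \code{model_state}.
#' @param Z n x d latent matrix.
#' @return n x m reconstruction.
#' @export
decode <- function(state, Z) {
  Z <- matrix(Z, ncol = state$d)
  pr <- state$params
  D1 <- dense_forward(Z, pr$Wd1, pr$bd1)
  addb(D1 %*% pr$Wd2, pr$bd2)
}

#' State-dependent transcription rate alpha = falpha(Zt)
#'
#' @param state a \code{model_state}.
#' @param Zt n x d latent states.
#' @return n x p matrix of transcription rates (positive when the model was
#'   configured with a softplus output).
#' @export
transcription_rate <- function(state, Zt) {
  Zt <- matrix(Zt, ncol = state$d)
  pr <- state$params
  A1 <- dense_forward(Zt, pr$Wa1, pr$ba1)
  raw <- addb(A1 %*% pr$Wa2, pr$ba2)
  if (state$cfg$alpha_nonneg) softplus(raw) else raw
}

#' Kinetic velocities from expression and rates
#'
#' Vu = alpha - beta U (unspliced velocity) and Vs = beta U - gamma S
#' (spliced RNA velocity), with gene-wise broadcast of beta and gamma.
#'
#' @param U,S n x p unspliced / spliced matrices.
#' @param alpha n x p transcription rates.
#' @param beta,gamma positive per-gene rate vectors.
#' @return A \code{velocity_estimate}: list(alpha, Vu, Vs).
#' @export
compute_velocity <- function(U, S, alpha, beta, gamma) {
  if (any(beta <= 0) || any(gamma <= 0))
    ve_stop("invalid-rates", "beta and gamma must be positive")
  stopifnot(all(dim(U) == dim(S)), all(dim(U) == dim(alpha)),
            ncol(U) == length(beta), ncol(U) == length(gamma))
  bU <- rowmult(U, beta)
  structure(list(alpha = alpha, Vu = alpha - bU, Vs = bU - rowmult(S, gamma)),
            class = "velocity_estimate")
}
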