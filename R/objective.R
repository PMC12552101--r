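# Loss terms. All are log-likelihood-style (<= 0, larger is better) and
# averaged per cell so the objective is batch-size invariant; the optimizer
# minimizes the negated total.

#' Loss weights
#' @param omega weight between the Z-path and Zt-path reconstructions, in
#'   (0,1); default 0.5.
#' @param lambda_v weight of the velocity losses; default 1.
#' @param q_omega percentile defining the high-expression penalty set Omega;
#'   default 95.
#' @export
loss_weights <- function(omega = 0.5, lambda_v = 1, q_omega = 95) {
  stopifnot(omega > 0, omega < 1, lambda_v >= 0, q_omega > 0, q_omega < 100)
  structure(list(omega = omega, lambda_v = lambda_v, q_omega = q_omega),
            class = "loss_weights")
}

#' Dual-path reconstruction loss Lt1
#'
#' \code{Lt1 = -omega ||X - Xhat_n||^2 - (1-omega) ||X - Xhat_t||^2},
#' summed over entries and averaged per cell; Xhat_n decodes the posterior
#' sample Z, Xhat_t the ODE-evolved Zt.
#' @param X,Xhat_n,Xhat_t matrices of equal shape.
#' @param omega weight in (0,1).
#' @export
loss_reconstruction <- function(X, Xhat_n, Xhat_t, omega = 0.5) {
  if (!all(dim(X) == dim(Xhat_n)) || !all(dim(X) == dim(Xhat_t)))
    ve_stop("shape-mismatch", "reconstruction shapes differ")
  n <- nrow(X)
  -(omega * sum((X - Xhat_n)^2) + (1 - omega) * sum((X - Xhat_t)^2)) / n
}

#' Negated KL divergence Lt2
#'
#' \code{Lt2 = -KL(N(mu, diag sigma^2) || N(0, I))
#'   = -0.5 sum(mu^2 + sigma^2 - 1 - log sigma^2)}, averaged per cell.
#' @param mu,log_sigma2 n x d posterior parameters.
#' @export
loss_kl <- function(mu, log_sigma2) {
  n <- nrow(as.matrix(mu))
  -0.5 * sum(mu^2 + exp(log_sigma2) - 1 - log_sigma2) / n
}

#' Latent-consistency loss Lt3
#'
#' Negated mean squared error between the posterior sample Z and the
#' ODE-evolved Zt, averaged per cell.
#' @param Z,Zt n x d matrices.
#' @export
loss_latent_consistency <- function(Z, Zt) {
  if (!all(dim(Z) == dim(Zt))) ve_stop("shape-mismatch", "Z and Zt differ")
  -sum((Z - Zt)^2) / nrow(Z)
}

#' Velocity reconstruction loss Lv1
#'
#' \code{Lv1 = -||Xsu - Xhat_su||^2} (per-cell average), where Xhat_su is the
#' segmented Euler reconstruction of (S, U) along pseudotime.
#' @param Xsu,Xhat_su n x 2p matrices.
#' @export
loss_velocity_reconstruction <- function(Xsu, Xhat_su) {
  if (!all(dim(Xsu) == dim(Xhat_su)))
    ve_stop("shape-mismatch", "Xsu and Xhat_su differ")
  -sum((Xsu - Xhat_su)^2) / nrow(Xsu)
}

#' High-expression penalty set Omega
#'
#' Entry (i, g) is in Omega iff the cell's expression of gene g strictly
#' exceeds the per-gene q-th percentile (linear-interpolation definition).
#' Expression defaults to S + U; cells near expression saturation are where
#' unspliced velocity should be small.
#'
#' @param S,U n x p matrices.
#' @param q percentile (default 95).
#' @param layer which expression the percentile is taken over:
#'   \code{"total"} (S + U, default), \code{"S"}, or \code{"U"}.
#' @return logical n x p mask.
#' @export
omega_mask <- function(S, U, q = 95, layer = c("total", "S", "U")) {
  layer <- match.arg(layer)
  E <- switch(layer, total = S + U, S = S, U = U)
  thr <- apply(E, 2L, stats::quantile, probs = q / 100, names = FALSE,
               type = 7)
  sweep(E, 2L, thr, ">")
}

#' Unspliced-velocity penalty Lv2
#'
#' \code{Lv2 = -sum_{(i,g) in Omega} Vu_{i,g}^2}, averaged per cell:
#' restrains the flexibility of the transcription-rate network where
#' expression is saturated.
#' @param Vu n x p unspliced velocities.
#' @param mask logical n x p penalty set.
#' @export
loss_unspliced_penalty <- function(Vu, mask) {
  if (!all(dim(Vu) == dim(mask))) ve_stop("shape-mismatch", "Vu and mask differ")
  -sum(Vu[mask]^2) / nrow(Vu)
}

#' Assemble the total objective
#'
#' \code{total = (Lt1 + Lt2 + Lt3) + lambda_v (Lv1 + Lv2)}; training
#' minimizes \code{-total}.
#' @param lt1,lt2,lt3,lv1,lv2 loss terms.
#' @param weights a \code{\link{loss_weights}}.
#' @return A \code{loss_breakdown} list with all terms and \code{total}.
#' @export
total_objective <- function(lt1, lt2, lt3, lv1, lv2,
                            weights = loss_weights()) {
  structure(list(lt1 = lt1, lt2 = lt2, lt3 = lt3, lv1 = lv1, lv2 = lv2,
                 total = (lt1 + lt2 + lt3) +
                   weights$lambda_v * (lv1 + lv2)),
            class = "loss_breakdown")
}
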