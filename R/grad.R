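# One training step's forward pass and hand-derived reverse-mode gradients.
#
# Computation graph per batch (n cells, m features, p genes, d latent dims):
#   H1 = elu(X W1 + b1)                       shared encoder layer
#   mu = H1 Wmu + bmu ; ls = H1 Wls + bls     posterior parameters
#   Z  = mu + exp(ls/2) * E                   reparameterized sample
#   t  = sigmoid((H1 Wt + bt) * t_sign)       pseudotime in (0,1)
#   Zt = Euler(fode, Zt0 = Z[argmin t], sorted t)   latent ODE
#   Xhat_n = fd(Z); Xhat_t = fd(Zt)           shared decoder
#   alpha  = softplus(falpha(Zt))             transcription rates
#   Xhat_su = segmented Euler recursion on (S, U) with V(alpha, beta, gamma)
#   losses Lt1..Lv2, total; minimized as -total.
#
# Gradients flow through everything differentiable, including the pseudotime
# increments dt inside both Euler recursions (sorting itself is piecewise
# constant). Verified against central finite differences in the test suite.

velode_step <- function(params, X, p, d, H, t_sign, opts, sample = TRUE,
                        want_grad = TRUE, E = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  omega <- opts$omega; lambda_v <- opts$lambda_v
  alpha_nonneg <- opts$alpha_nonneg

  ## ---- forward ----
  H1 <- dense_forward(X, params$W1, params$b1)
  mu <- addb(H1 %*% params$Wmu, params$bmu)
  ls_raw <- addb(H1 %*% params$Wls, params$bls)
  ls <- clamp_ls(ls_raw)
  if (is.null(E)) E <- if (sample) matrix(stats::rnorm(n * d), n, d) else matrix(0, n, d)
  sig <- exp(ls / 2)
  Z <- if (sample) mu + sig * E else mu
  traw <- drop(H1 %*% params$Wt + params$bt[1L]) * t_sign
  tt <- sigmoid(traw)
  ord <- order(tt, seq_len(n))
  ts <- tt[ord]

  # latent ODE, explicit Euler over sorted pseudotime
  Azt <- matrix(0, n, d)
  G1ode <- matrix(0, n, H)   # hidden activations, row k = step input k
  Fode <- matrix(0, n, d)    # drift values
  Azt[1L, ] <- Z[ord[1L], ]
  if (n > 1L) for (k in 2:n) {
    z <- Azt[k - 1L, ]
    g <- elu(drop(z %*% params$Wo1) + params$bo1)
    f <- drop(g %*% params$Wo2) + params$bo2
    G1ode[k - 1L, ] <- g
    Fode[k - 1L, ] <- f
    Azt[k, ] <- z + f * (ts[k] - ts[k - 1L])
  }
  Zt <- matrix(0, n, d)
  Zt[ord, ] <- Azt

  # decoder on both paths (same parameters)
  D1n <- dense_forward(Z, params$Wd1, params$bd1)
  Xhat_n <- addb(D1n %*% params$Wd2, params$bd2)
  D1t <- dense_forward(Zt, params$Wd1, params$bd1)
  Xhat_t <- addb(D1t %*% params$Wd2, params$bd2)

  # transcription rate
  A1a <- dense_forward(Zt, params$Wa1, params$ba1)
  alpha_raw <- addb(A1a %*% params$Wa2, params$ba2)
  alpha <- if (alpha_nonneg) softplus(alpha_raw) else alpha_raw

  beta <- exp(params$log_beta)
  gamma <- exp(params$log_gamma)
  Sobs <- X[, seq_len(p), drop = FALSE]
  Uobs <- X[, p + seq_len(p), drop = FALSE]

  # unspliced velocity at observed expression, with the Omega penalty mask
  Vu_obs <- alpha - rowmult(Uobs, beta)
  mask <- omega_mask(Sobs, Uobs, opts$q_omega, layer = opts$omega_layer)

  # segmented Euler reconstruction of (S, U), sorted order
  segs <- segment_lengths(n, opts$interval_l)
  Ssort <- Sobs[ord, , drop = FALSE]
  Usort <- Uobs[ord, , drop = FALSE]
  alsort <- alpha[ord, , drop = FALSE]
  rec <- euler_recon_sorted(Ssort, Usort, ts, alsort, beta, gamma, segs)

  lt1 <- loss_reconstruction(X, Xhat_n, Xhat_t, omega)
  lt2 <- loss_kl(mu, ls)
  lt3 <- loss_latent_consistency(Z, Zt)
  lv1 <- loss_velocity_reconstruction(cbind(Ssort, Usort),
                                      cbind(rec$Sh, rec$Uh))
  lv2 <- loss_unspliced_penalty(Vu_obs, mask)
  breakdown <- total_objective(lt1, lt2, lt3, lv1, lv2,
                               loss_weights(omega, lambda_v, opts$q_omega))
  out <- list(loss = -breakdown$total, breakdown = breakdown,
              t = tt, order = ord, mu = mu, log_sigma2 = ls, Z = Z, Zt = Zt,
              alpha = alpha, Xhat_n = Xhat_n, Xhat_t = Xhat_t)
  if (!want_grad) return(out)

  ## ---- backward (gradients of -total) ----
  g0 <- vector("list", length(params)); names(g0) <- names(params)
  dT <- numeric(n)        # d(-total)/d t (original order, accumulated sorted)
  dT_sorted <- numeric(n)
  dZ <- matrix(0, n, d)
  dZt <- matrix(0, n, d)
  dbeta <- numeric(p); dgamma <- numeric(p)

  # Lt1 -> decoder paths
  dXhat_n <- (2 * omega / n) * (Xhat_n - X)
  dXhat_t <- (2 * (1 - omega) / n) * (Xhat_t - X)
  bn <- dense_backward(D1n, NULL, dXhat_n, params$Wd2, act = FALSE)
  # bn$dX is gradient wrt D1n
  bn2 <- dense_backward(Z, D1n, bn$dX, params$Wd1, act = TRUE)
  bt_ <- dense_backward(D1t, NULL, dXhat_t, params$Wd2, act = FALSE)
  bt2 <- dense_backward(Zt, D1t, bt_$dX, params$Wd1, act = TRUE)
  g0$Wd2 <- bn$dW + bt_$dW; g0$bd2 <- bn$db + bt_$db
  g0$Wd1 <- bn2$dW + bt2$dW; g0$bd1 <- bn2$db + bt2$db
  dZ <- dZ + bn2$dX
  dZt <- dZt + bt2$dX

  # Lt3
  dZ <- dZ + (2 / n) * (Z - Zt)
  dZt <- dZt - (2 / n) * (Z - Zt)

  # Lt2 (KL)
  dmu <- mu / n
  dls <- 0.5 * (exp(ls) - 1) / n

  # Lv2 -> alpha, beta
  dalpha <- matrix(0, n, p)
  dVu <- (2 * lambda_v / n) * (Vu_obs * mask)
  dalpha <- dalpha + dVu
  dbeta <- dbeta - colSums(Uobs * dVu)

  # Lv1 -> Euler reconstruction backward (sorted space)
  dSh <- (2 * lambda_v / n) * (rec$Sh - Ssort)
  dUh <- (2 * lambda_v / n) * (rec$Uh - Usort)
  dalpha_sorted <- matrix(0, n, p)
  pos <- 0L
  for (len in segs) {
    if (len > 1L) {
      aU <- numeric(p); aS <- numeric(p)
      for (k in (pos + len):(pos + 2L)) {
        aU <- aU + dUh[k, ]; aS <- aS + dSh[k, ]
        dt <- ts[k] - ts[k - 1L]
        Up <- rec$Uh[k - 1L, ]; Sp <- rec$Sh[k - 1L, ]
        ap <- alsort[k - 1L, ]
        Vu <- ap - beta * Up
        Vs <- beta * Up - gamma * Sp
        ddt <- sum(aU * Vu) + sum(aS * Vs)
        dT_sorted[k] <- dT_sorted[k] + ddt
        dT_sorted[k - 1L] <- dT_sorted[k - 1L] - ddt
        dalpha_sorted[k - 1L, ] <- dalpha_sorted[k - 1L, ] + aU * dt
        dbeta <- dbeta + dt * Up * (aS - aU)
        dgamma <- dgamma - dt * Sp * aS
        newAU <- aU * (1 - beta * dt) + aS * (beta * dt)
        aS <- aS * (1 - gamma * dt)
        aU <- newAU
      }
      # adjoint at the segment's first cell hits observed data: stop
    }
    pos <- pos + len
  }
  dalpha[ord, ] <- dalpha[ord, , drop = FALSE] + dalpha_sorted

  # alpha network backward -> dZt
  dalpha_raw <- if (alpha_nonneg) dalpha * sigmoid(alpha_raw) else dalpha
  ba2_ <- dense_backward(A1a, NULL, dalpha_raw, params$Wa2, act = FALSE)
  ba1_ <- dense_backward(Zt, A1a, ba2_$dX, params$Wa1, act = TRUE)
  g0$Wa2 <- ba2_$dW; g0$ba2 <- ba2_$db
  g0$Wa1 <- ba1_$dW; g0$ba1 <- ba1_$db
  dZt <- dZt + ba1_$dX

  # latent ODE backward (adjoint sweep over sorted steps)
  dZt_sorted <- dZt[ord, , drop = FALSE]
  DF <- matrix(0, n, d); Dh <- matrix(0, n, H)
  a <- numeric(d)
  if (n > 1L) for (k in n:2) {
    a <- a + dZt_sorted[k, ]
    dtk <- ts[k] - ts[k - 1L]
    dF <- a * dtk
    gact <- G1ode[k - 1L, ]
    dh <- drop(dF %*% t(params$Wo2)) * elu_deriv_from_act(gact)
    DF[k - 1L, ] <- dF
    Dh[k - 1L, ] <- dh
    ddt <- sum(a * Fode[k - 1L, ])
    dT_sorted[k] <- dT_sorted[k] + ddt
    dT_sorted[k - 1L] <- dT_sorted[k - 1L] - ddt
    a <- a + drop(dh %*% t(params$Wo1))
  }
  a <- a + dZt_sorted[1L, ]
  dZ[ord[1L], ] <- dZ[ord[1L], ] + a
  idx <- seq_len(max(n - 1L, 1L))
  g0$Wo2 <- crossprod(G1ode[idx, , drop = FALSE], DF[idx, , drop = FALSE])
  g0$bo2 <- colSums(DF)
  g0$Wo1 <- crossprod(Azt[idx, , drop = FALSE], Dh[idx, , drop = FALSE])
  g0$bo1 <- colSums(Dh)

  # pseudotime backward: t = sigmoid(traw * 1) with traw scaled by t_sign
  dT[ord] <- dT_sorted
  dtraw <- dT * tt * (1 - tt) * t_sign
  g0$Wt <- crossprod(H1, matrix(dtraw, n, 1L))
  g0$bt <- sum(dtraw)
  dH1 <- tcrossprod(matrix(dtraw, n, 1L), params$Wt)

  # reparameterization: Z = mu + exp(ls/2) E
  dmu <- dmu + dZ
  if (sample) dls <- dls + dZ * E * sig * 0.5
  dls <- dls * (abs(ls_raw) < 30)   # clamp is flat outside its bounds
  g0$Wmu <- crossprod(H1, dmu); g0$bmu <- colSums(dmu)
  g0$Wls <- crossprod(H1, dls); g0$bls <- colSums(dls)
  dH1 <- dH1 + tcrossprod(dmu, params$Wmu) + tcrossprod(dls, params$Wls)
  b1_ <- dense_backward(X, H1, dH1, params$W1, act = TRUE)
  g0$W1 <- b1_$dW; g0$b1 <- b1_$db

  # log-scale kinetic parameters
  g0$log_beta <- dbeta * beta
  g0$log_gamma <- dgamma * gamma

  out$grads <- g0
  out
}

# consecutive segment sizes for n sorted cells with interval l
# (trailing singleton merged into the previous segment)
segment_lengths <- function(n, l) {
  sizes <- rep(l, n %/% l)
  r <- n %% l
  if (r > 0L) sizes <- c(sizes, r)
  k <- length(sizes)
  if (k > 1L && sizes[k] == 1L) {
    sizes[k - 1L] <- sizes[k - 1L] + 1L
    sizes <- sizes[-k]
  }
  sizes
}
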