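#' Training configuration
#'
#' Optimizer defaults follow the reference setting for this model family:
#' Adam with learning rate 0.01, weight decay 0.01, epsilon 0.01, AMSGrad
#' enabled, batch size 1024 (capped at n).
#'
#' @param batch_size mini-batch size (default 1024; capped at the number of
#'   cells).
#' @param epochs training epochs (default 400).
#' @param lr,weight_decay,adam_eps,amsgrad Adam settings.
#' @param lambda_u,lambda_s direction-correction weights in (0,1);
#'   equal weights 0.5 by default.
#' @param seed integer controlling all fit randomness (init, shuffling,
#'   posterior sampling).
#' @param early_stop_patience stop when the total loss has not improved for
#'   this many epochs (default 30).
#' @param interval_l Euler reconstruction segment length (default 50).
#' @param knn_k neighborhood size for the velocity-pseudotime check.
#' @param direction_correction apply the post-hoc Pearson flip rule.
#' @param retrain_on_inconsistency retrain once from a reversed pseudotime
#'   initialization when the velocity pseudotime disagrees in sign with the
#'   fitted pseudotime.
#' @export
train_config <- function(batch_size = 1024L, epochs = 400L, lr = 0.01,
                         weight_decay = 0.01, adam_eps = 0.01, amsgrad = TRUE,
                         lambda_u = 0.5, lambda_s = 0.5, seed = 0L,
                         early_stop_patience = 30L, interval_l = 50L,
                         knn_k = 30L, direction_correction = TRUE,
                         retrain_on_inconsistency = TRUE) {
  stopifnot(batch_size >= 2, epochs >= 0, lambda_u > 0, lambda_u < 1,
            lambda_s > 0, lambda_s < 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay, adam_eps = adam_eps,
                 amsgrad = isTRUE(amsgrad), lambda_u = lambda_u,
                 lambda_s = lambda_s, seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience),
                 interval_l = as.integer(interval_l),
                 knn_k = as.integer(knn_k),
                 direction_correction = isTRUE(direction_correction),
                 retrain_on_inconsistency = isTRUE(retrain_on_inconsistency)),
            class = "train_config")
}

step_opts <- function(weights, tcfg, mcfg) {
  list(omega = weights$omega, lambda_v = weights$lambda_v,
       q_omega = weights$q_omega, omega_layer = "total",
       alpha_nonneg = mcfg$alpha_nonneg, interval_l = tcfg$interval_l)
}

# evaluation-mode forward pass: posterior means, full-data latent ODE,
# velocities at the observed (smoothed) layers; applies the stored flip
eval_forward <- function(state, ds, interval_l = 50L) {
  X <- feature_matrix(ds)
  enc <- encode(state, X, sample = FALSE)
  ord <- enc$order
  Zt0 <- enc$mu[ord[1L], ]
  Azt <- integrate_latent(state, Zt0, enc$t[ord])
  Zt <- matrix(0, nrow(X), state$d)
  Zt[ord, ] <- Azt
  alpha <- transcription_rate(state, Zt)
  rates <- kinetic_rates(state)
  vel <- compute_velocity(ds$U, ds$S, alpha, rates$beta, rates$gamma)
  tt <- enc$t
  if (isTRUE(state$flipped)) {
    tt <- 1 - tt
    vel$Vu <- -vel$Vu
    vel$Vs <- -vel$Vs
  }
  list(t = tt, velocity = vel, Zt = Zt, Z = enc$mu,
       log_sigma2 = enc$log_sigma2)
}

run_training <- function(ds, mcfg, weights, tcfg, t_sign) {
  X <- feature_matrix(ds)
  n <- nrow(X); p <- ncol(ds$S)
  state <- init_model(mcfg, p, ncol(X))
  state$t_sign <- t_sign
  opts <- step_opts(weights, tcfg, mcfg)
  opt <- adam_init(state$params)
  bs <- min(tcfg$batch_size, n)
  set.seed(derive_seed(tcfg$seed, "fit"))
  hist <- vector("list", tcfg$epochs)
  best <- Inf; stall <- 0L
  n_epochs_run <- 0L
  for (epoch in seq_len(tcfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    acc <- c(lt1 = 0, lt2 = 0, lt3 = 0, lv1 = 0, lv2 = 0, total = 0)
    for (s in starts) {
      idx <- perm[s:min(s + bs - 1L, n)]
      if (length(idx) < 2L) next
      res <- velode_step(state$params, X[idx, , drop = FALSE], p, state$d,
                         state$H, state$t_sign, opts, sample = TRUE,
                         want_grad = TRUE)
      if (!is.finite(res$loss))
        ve_stop("training-diverged", "non-finite loss at epoch %d", epoch)
      upd <- adam_step(state$params, res$grads, opt, lr = tcfg$lr,
                       eps = tcfg$adam_eps,
                       weight_decay = tcfg$weight_decay,
                       amsgrad = tcfg$amsgrad)
      state$params <- upd$params
      opt <- upd$state
      w <- length(idx) / n
      b <- res$breakdown
      acc <- acc + w * c(b$lt1, b$lt2, b$lt3, b$lv1, b$lv2, b$total)
    }
    hist[[epoch]] <- acc
    n_epochs_run <- epoch
    if (-acc[["total"]] < best - 1e-10) {
      best <- -acc[["total"]]; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tcfg$early_stop_patience) break
    }
  }
  hist <- hist[seq_len(n_epochs_run)]
  loss_history <- if (n_epochs_run > 0L)
    data.frame(epoch = seq_len(n_epochs_run), do.call(rbind, hist))
  else {
    # zero-epoch fit: record one evaluation-mode loss row
    res <- velode_step(state$params, X, p, state$d, state$H, state$t_sign,
                       opts, sample = FALSE, want_grad = FALSE)
    b <- res$breakdown
    data.frame(epoch = 0L, lt1 = b$lt1, lt2 = b$lt2, lt3 = b$lt3,
               lv1 = b$lv1, lv2 = b$lv2, total = b$total)
  }
  list(state = state, loss_history = loss_history)
}

#' Fit the joint pseudotime / RNA velocity model
#'
#' Trains the variational autoencoder with latent-ODE dynamics and the
#' kinetic velocity head by mini-batch gradient descent, then produces
#' final pseudotime and velocities from an evaluation-mode pass (posterior
#' means, no sampling), applies the Pearson direction correction, and - if
#' the velocity pseudotime disagrees in sign with the fitted pseudotime -
#' retrains once from a reversed pseudotime initialization. Fully
#' deterministic under the training seed.
#'
#' @param ds a preprocessed \code{\link{omics_dataset}} (see
#'   \code{\link{preprocess_dataset}}).
#' @param model a \code{\link{model_config}}.
#' @param weights a \code{\link{loss_weights}}.
#' @param control a \code{\link{train_config}}.
#' @return An object of class \code{velode}: the fitted model state,
#'   per-cell pseudotime \code{t} in (0,1), a \code{velocity} estimate
#'   (alpha, Vu, Vs at the observed smoothed layers), flags
#'   \code{flipped}/\code{retrained}, and the per-epoch loss history.
#' @seealso \code{\link{predict.velode}}, \code{\link{direction_correction}},
#'   \code{\link{velocity_pseudotime_check}}
#' @export
velode <- function(ds, model = model_config(), weights = loss_weights(),
                   control = train_config()) {
  stopifnot(inherits(ds, "omics_dataset"))
  if (nrow(ds$S) < 4L) ve_stop("too-few-cells", "need at least 4 cells")
  fitted1 <- run_training(ds, model, weights, control, t_sign = 1)
  out <- finalize_fit(fitted1, ds, control, retrained = FALSE)
  if (control$retrain_on_inconsistency && control$epochs > 0L) {
    chk <- velocity_pseudotime_check(out$t, out$velocity, ds,
                                     knn_k = control$knn_k)
    if (!chk$consistent) {
      fitted2 <- run_training(ds, model, weights, control, t_sign = -1)
      out <- finalize_fit(fitted2, ds, control, retrained = TRUE)
    }
  }
  out$model_config <- model
  out$weights <- weights
  out$control <- control
  out$data <- ds
  out$call <- match.call()
  out
}

finalize_fit <- function(fitted, ds, control, retrained) {
  state <- fitted$state
  state$flipped <- FALSE
  ev <- eval_forward(state, ds, control$interval_l)
  flipped <- FALSE
  if (control$direction_correction) {
    dc <- direction_correction(ev$velocity$Vs, ds$U, ds$S,
                               control$lambda_u, control$lambda_s)
    if (dc$flip) {
      flipped <- TRUE
      state$flipped <- TRUE
      ev$t <- 1 - ev$t
      ev$velocity$Vu <- -ev$velocity$Vu
      ev$velocity$Vs <- -ev$velocity$Vs
    }
  }
  structure(list(state = state, t = ev$t, velocity = ev$velocity,
                 Zt = ev$Zt, Z = ev$Z, flipped = flipped,
                 retrained = retrained,
                 loss_history = fitted$loss_history),
            class = "velode")
}

#' Post-hoc direction correction from the spliced-unspliced relationship
#'
#' Because \code{Vs = beta U - gamma S}, the spliced velocity of a cell
#' should correlate positively with its unspliced and negatively with its
#' spliced expression across genes. The score
#' \code{LPearson = mean_i [lambda_u corr(Vs_i, U_i) - lambda_s corr(Vs_i, S_i)]}
#' is computed per cell and averaged; a negative score indicates the ODE was
#' solved along reversed time, and the caller flips t to 1 - t and negates
#' the velocities. \code{mode = "global"} computes one correlation over all
#' entries instead.
#'
#' @param Vs n x p spliced velocities.
#' @param U,S n x p observed layers.
#' @param lambda_u,lambda_s weights in (0,1).
#' @param mode \code{"per_cell"} (default) or \code{"global"}.
#' @return list(flip = logical, l_pearson = score).
#' @export
direction_correction <- function(Vs, U, S, lambda_u = 0.5, lambda_s = 0.5,
                                 mode = c("per_cell", "global")) {
  mode <- match.arg(mode)
  stopifnot(all(dim(Vs) == dim(U)), all(dim(Vs) == dim(S)))
  if (mode == "global") {
    lp <- lambda_u * safe_cor(as.vector(Vs), as.vector(U)) -
      lambda_s * safe_cor(as.vector(Vs), as.vector(S))
    if (is.na(lp)) ve_stop("degenerate-correlation", "constant inputs")
    return(list(flip = lp < 0, l_pearson = lp))
  }
  n <- nrow(Vs)
  scores <- vapply(seq_len(n), function(i) {
    cu <- safe_cor(Vs[i, ], U[i, ])
    cs <- safe_cor(Vs[i, ], S[i, ])
    if (is.na(cu) || is.na(cs)) return(NA_real_)
    lambda_u * cu - lambda_s * cs
  }, numeric(1))
  if (all(is.na(scores)))
    ve_stop("degenerate-correlation", "all cells have constant rows")
  if (anyNA(scores))
    ve_warn("%d cells with constant rows skipped in direction correction",
            sum(is.na(scores)))
  lp <- mean(scores, na.rm = TRUE)
  list(flip = lp < 0, l_pearson = lp)
}

# k nearest neighbors by Euclidean distance, excluding self
knn_exclude_self <- function(M, k) {
  D <- as.matrix(stats::dist(M))
  diag(D) <- Inf
  res <- vapply(seq_len(nrow(M)), function(i) order(D[i, ])[seq_len(k)],
                integer(k))
  if (k == 1L) matrix(res, nrow(M), 1L) else t(res)
}

#' Velocity-pseudotime consistency check
#'
#' Builds a KNN graph on smoothed spliced expression, scores each cell's
#' transitions to its neighbors by the cosine similarity between its spliced
#' velocity and the expression displacement S_j - S_i (softmax-normalized),
#' evolves a uniform distribution under the transition operator to a
#' stationary-style score (tolerance 1e-8, at most 1000 iterations, with a
#' small uniform restart for ergodicity), and rank-normalizes it into a
#' velocity pseudotime. The fit is consistent when this velocity pseudotime
#' correlates non-negatively with the model's pseudotime; zero velocities
#' give an undefined correlation and are treated as consistent with a
#' warning.
#'
#' @param t fitted pseudotime.
#' @param velocity a \code{velocity_estimate} (or list with \code{Vs}).
#' @param ds the (smoothed) dataset the model was fitted on.
#' @param knn_k neighborhood size.
#' @param damping uniform-restart probability (default 0.05).
#' @return list(consistent, corr, velocity_pseudotime).
#' @export
velocity_pseudotime_check <- function(t, velocity, ds, knn_k = 30L,
                                      damping = 0.05) {
  S <- ds$S
  n <- nrow(S)
  k <- min(knn_k, n - 1L)
  Vs <- velocity$Vs
  if (all(Vs == 0)) {
    ve_warn("all velocities are zero; velocity pseudotime degenerate, treating direction as consistent")
    return(list(consistent = TRUE, corr = NA_real_,
                velocity_pseudotime = rep(0.5, n)))
  }
  nbr <- knn_exclude_self(S, k)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    v <- Vs[i, ]
    nv <- sqrt(sum(v^2))
    js <- nbr[i, ]
    disp <- S[js, , drop = FALSE] - matrix(S[i, ], k, ncol(S), byrow = TRUE)
    dn <- sqrt(rowSums(disp^2))
    cosv <- if (nv == 0) rep(0, k) else
      as.vector(disp %*% v) / (pmax(dn, 1e-12) * nv)
    w <- exp(cosv - max(cosv))
    P[i, js] <- w / sum(w)
  }
  # connectivity check on the undirected KNN graph
  comp <- graph_components(nbr, n)
  use <- rep(TRUE, n)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    use <- comp == which.max(sizes)
    ve_warn("KNN graph disconnected; using largest component (%d of %d cells)",
            sum(use), n)
  }
  x <- rep(1 / n, n)
  for (iter in seq_len(1000L)) {
    xn <- (1 - damping) * drop(crossprod(P, x)) + damping / n
    if (max(abs(xn - x)) < 1e-8) { x <- xn; break }
    x <- xn
  }
  vpt <- rank(x, ties.method = "average") / n
  corr <- safe_cor(vpt[use], t[use])
  if (is.na(corr)) {
    ve_warn("velocity pseudotime degenerate; treating direction as consistent")
    return(list(consistent = TRUE, corr = NA_real_,
                velocity_pseudotime = vpt))
  }
  list(consistent = corr >= 0, corr = corr, velocity_pseudotime = vpt)
}

graph_components <- function(nbr, n) {
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    adj[[i]] <- c(adj[[i]], nbr[i, ])
    for (j in nbr[i, ]) adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (u in adj[[v]]) if (comp[u] == 0L) {
        comp[u] <- cur
        queue <- c(queue, u)
      }
    }
  }
  comp
}

#' Predict pseudotime and velocity for (possibly unseen) cells
#'
#' Deterministic evaluation-mode forward pass: posterior means, latent ODE
#' over the cells' own pseudotime ordering, velocities at the supplied
#' (smoothed) layers. The direction correction learned during fitting is
#' applied. On the training data this reproduces the fit's outputs exactly.
#'
#' @param object a fitted \code{velode} model.
#' @param newdata an \code{\link{omics_dataset}} with the same features the
#'   model was trained on; defaults to the training data.
#' @param ... unused.
#' @return list(t, velocity, Zt).
#' @export
predict.velode <- function(object, newdata = NULL, ...) {
  ds <- newdata %||% object$data
  if (ncol(feature_matrix(ds)) != object$state$m)
    ve_stop("shape-mismatch", "newdata features do not match the model")
  ev <- eval_forward(object$state, ds, object$control$interval_l)
  list(t = ev$t, velocity = ev$velocity, Zt = ev$Zt)
}
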