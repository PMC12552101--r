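#' Partition cells into pseudotime segments
#'
#' Cells are sorted by t ascending (stable; ties broken by original index)
#' and split into consecutive segments of \code{interval_l} cells. The last
#' segment may be shorter but keeps at least two cells: a leftover singleton
#' is merged into the previous segment. Segment resets bound the error the
#' explicit Euler recursion accumulates along pseudotime.
#'
#' @param t per-cell pseudotime.
#' @param interval_l segment length (default 50).
#' @return list of integer vectors of *original* cell indices, each sorted by t.
#' @export
segment_by_time <- function(t, interval_l = 50L) {
  n <- length(t)
  if (n < 2L) ve_stop("too-few-cells", "need at least 2 cells, got %d", n)
  stopifnot(interval_l >= 2L, all(is.finite(t)))
  ord <- order(t, seq_len(n))
  starts <- seq(1L, n, by = interval_l)
  segs <- lapply(starts, function(s) ord[s:min(s + interval_l - 1L, n)])
  k <- length(segs)
  if (k > 1L && length(segs[[k]]) == 1L) {
    segs[[k - 1L]] <- c(segs[[k - 1L]], segs[[k]])
    segs[[k]] <- NULL
  }
  segs
}

# internal workhorse shared by euler_reconstruct() and the training step:
# operates on matrices already sorted by pseudotime; returns sorted-order
# reconstructions of S and U
euler_recon_sorted <- function(Ssort, Usort, ts, alpha_sort, beta, gamma,
                               seg_sizes) {
  n <- nrow(Ssort)
  Sh <- Ssort; Uh <- Usort
  pos <- 0L
  for (len in seg_sizes) {
    first <- pos + 1L
    if (len > 1L) for (k in (first + 1L):(pos + len)) {
      dt <- ts[k] - ts[k - 1L]
      Up <- Uh[k - 1L, ]; Sp <- Sh[k - 1L, ]
      Vu <- alpha_sort[k - 1L, ] - beta * Up
      Vs <- beta * Up - gamma * Sp
      Uh[k, ] <- Up + Vu * dt
      Sh[k, ] <- Sp + Vs * dt
    }
    pos <- pos + len
  }
  list(Sh = Sh, Uh = Uh)
}

#' Segmented Euler reconstruction of expression along pseudotime
#'
#' Within each pseudotime segment the first cell's reconstruction equals its
#' observation; each subsequent cell is predicted from the previous
#' reconstruction by one Euler step of the kinetic ODEs, with the
#' transcription rate taken from the previous cell's latent state:
#' \code{Xhat_k = Xhat_{k-1} + Vhat(t_{k-1}) * (t_k - t_{k-1})}. Velocities
#' inside the recursion are evaluated at the *running* estimates, and
#' negative running values are not clipped (so the objective can penalize
#' them).
#'
#' @param Xsu n x 2p observed matrix, columns (S, U).
#' @param t per-cell pseudotime.
#' @param Zt n x d latent states (row-aligned with \code{Xsu}).
#' @param state a \code{model_state} supplying falpha, beta, gamma.
#' @param interval_l segment length (default 50).
#' @return n x 2p reconstruction in the original cell order.
#' @export
euler_reconstruct <- function(Xsu, t, Zt, state, interval_l = 50L) {
  Xsu <- as.matrix(Xsu)
  p <- state$p
  if (ncol(Xsu) != 2L * p || nrow(Xsu) != length(t) ||
      nrow(Zt) != length(t))
    ve_stop("shape-mismatch", "Xsu, t and Zt must be row-aligned with 2p columns")
  segs <- segment_by_time(t, interval_l)
  ord <- unlist(segs)
  rates <- kinetic_rates(state)
  alpha <- transcription_rate(state, Zt)
  rec <- euler_recon_sorted(Xsu[ord, seq_len(p), drop = FALSE],
                            Xsu[ord, p + seq_len(p), drop = FALSE],
                            t[ord], alpha[ord, , drop = FALSE],
                            rates$beta, rates$gamma, lengths(segs))
  out <- matrix(0, nrow(Xsu), 2L * p)
  out[ord, ] <- cbind(rec$Sh, rec$Uh)
  out
}
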