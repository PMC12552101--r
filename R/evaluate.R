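# Benchmark metrics for pseudotime and velocity accuracy.

#' Pearson correlation between estimated and true pseudotime
#' @param t_est,t_true numeric vectors of equal length (>= 3).
#' @export
pearson_pseudotime <- function(t_est, t_true) {
  stopifnot(length(t_est) == length(t_true), length(t_est) >= 3)
  r <- safe_cor(t_est, t_true)
  if (is.na(r)) ve_stop("degenerate", "constant pseudotime")
  r
}

#' Circular cross-correlation of pseudotime on cyclic trajectories
#'
#' Maximizes the Pearson correlation of \code{t_est} against
#' \code{frac(sigma * t_true + tau)} over a grid of n circular offsets tau
#' and both orientations sigma = +/-1, so the score is invariant to where
#' the cycle starts and which way it runs.
#'
#' @param t_est,t_true values in [0, 1).
#' @return maximum correlation, in [-1, 1].
#' @export
circular_cross_correlation <- function(t_est, t_true) {
  n <- length(t_est)
  stopifnot(length(t_true) == n, n >= 3)
  if (stats::sd(t_est) == 0) ve_stop("degenerate", "constant pseudotime")
  taus <- (seq_len(n) - 1L) / n
  best <- -1
  for (sg in c(1, -1)) {
    base <- sg * t_true
    for (tau in taus) {
      r <- safe_cor(t_est, frac01(base + tau))
      if (!is.na(r) && r > best) best <- r
    }
  }
  best
}

#' Per-cell velocity correlation
#'
#' For each cell, the Pearson correlation across genes between estimated and
#' true spliced velocities; the mean over cells is returned (cells with a
#' constant row in either matrix are skipped).
#' @param Vs_est,Vs_true n x p matrices.
#' @export
velocity_correlation <- function(Vs_est, Vs_true) {
  stopifnot(all(dim(Vs_est) == dim(Vs_true)))
  rs <- vapply(seq_len(nrow(Vs_est)), function(i)
    safe_cor(Vs_est[i, ], Vs_true[i, ]), numeric(1))
  if (all(is.na(rs))) ve_stop("degenerate", "all cells degenerate")
  mean(rs, na.rm = TRUE)
}

#' Per-cell cosine similarity between two velocity fields
#'
#' Used to quantify stability of the velocity estimate under perturbations
#' of the input data (thinning, down-sampling, removed cell types).
#' @param Vs_a,Vs_b n x p matrices (aligned cells).
#' @return length-n vector of cosine similarities; zero rows give 0 with a
#'   warning.
#' @export
stability_cosine <- function(Vs_a, Vs_b) {
  stopifnot(all(dim(Vs_a) == dim(Vs_b)))
  na <- sqrt(rowSums(Vs_a^2)); nb <- sqrt(rowSums(Vs_b^2))
  zero <- na == 0 | nb == 0
  if (any(zero)) ve_warn("%d zero-velocity cells scored 0", sum(zero))
  out <- rowSums(Vs_a * Vs_b) / (pmax(na, 1e-300) * pmax(nb, 1e-300))
  out[zero] <- 0
  out
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# transition-probability projection of high-dimensional velocities onto a
# 2-D embedding: cosine scores over KNN, softmax, expected displacement
project_velocity_embedding <- function(Vs, S, embedding, knn_k = 30L) {
  n <- nrow(S)
  k <- min(knn_k, n - 1L)
  nbr <- knn_exclude_self(S, k)
  arrows <- matrix(0, n, 2L)
  for (i in seq_len(n)) {
    js <- nbr[i, ]
    disp <- S[js, , drop = FALSE] - matrix(S[i, ], k, ncol(S), byrow = TRUE)
    cosv <- vapply(seq_len(k), function(r) cosine(Vs[i, ], disp[r, ]),
                   numeric(1))
    w <- exp(cosv - max(cosv)); w <- w / sum(w)
    edisp <- embedding[js, , drop = FALSE] -
      matrix(embedding[i, ], k, 2L, byrow = TRUE)
    arrows[i, ] <- colSums(w * edisp)
  }
  arrows
}

#' Cross-boundary direction and length metrics
#'
#' Scores a velocity field against declared ground-truth cell-type
#' transitions. Boundary cells are from-label cells with at least one
#' to-label cell among their k nearest neighbors (in smoothed spliced
#' expression space).
#' \itemize{
#'   \item \code{cbdir}: mean cosine similarity, in embedding space, between
#'     a boundary cell's projected velocity arrow and its displacements to
#'     to-label neighbors.
#'   \item \code{cbdir2}: the same construction in high-dimensional
#'     expression space (Vs against S_j - S_i), no projection.
#'   \item \code{transcosine}: mean cosine similarity between a boundary
#'     cell's velocity-derived neighbor transition-probability vector
#'     (softmax of expression-space cosine scores) and the indicator of its
#'     to-label neighbors, rescaled to [-1, 1].
#'   \item \code{lenacc}: Pearson correlation over cells between ||Vs_i||
#'     and the mean displacement norm to the cell's k forward (later
#'     pseudotime-free: all) neighbors.
#' }
#'
#' @param Vs n x p spliced velocities.
#' @param S_smoothed n x p smoothed spliced expression.
#' @param embedding n x 2 embedding (required for \code{cbdir}; \code{NA}
#'   returned when absent).
#' @param cell_labels per-cell labels.
#' @param transitions list of c(from, to) label pairs (or "A>B" strings).
#' @param knn_k neighborhood size (default 30).
#' @return list(cbdir, cbdir2, transcosine, lenacc).
#' @export
boundary_metrics <- function(Vs, S_smoothed, embedding, cell_labels,
                             transitions, knn_k = 30L) {
  n <- nrow(S_smoothed)
  if (is.character(transitions))
    transitions <- strsplit(transitions, ">", fixed = TRUE)
  if (!is.list(transitions)) transitions <- list(transitions)
  k <- min(knn_k, n - 1L)
  nbr <- knn_exclude_self(S_smoothed, k)
  arrows <- if (!is.null(embedding))
    project_velocity_embedding(Vs, S_smoothed, embedding, k) else NULL
  cb1 <- c(); cb2 <- c(); tc <- c()
  any_boundary <- FALSE
  for (tr in transitions) {
    from <- tr[[1]]; to <- tr[[2]]
    cells <- which(cell_labels == from)
    used <- FALSE
    for (i in cells) {
      js <- nbr[i, ]
      hit <- cell_labels[js] == to
      if (!any(hit)) next
      used <- TRUE; any_boundary <- TRUE
      disp <- S_smoothed[js[hit], , drop = FALSE] -
        matrix(S_smoothed[i, ], sum(hit), ncol(S_smoothed), byrow = TRUE)
      cb2 <- c(cb2, mean(vapply(seq_len(nrow(disp)), function(r)
        cosine(Vs[i, ], disp[r, ]), numeric(1))))
      if (!is.null(arrows)) {
        edisp <- embedding[js[hit], , drop = FALSE] -
          matrix(embedding[i, ], sum(hit), 2L, byrow = TRUE)
        cb1 <- c(cb1, mean(vapply(seq_len(nrow(edisp)), function(r)
          cosine(arrows[i, ], edisp[r, ]), numeric(1))))
      }
      alldisp <- S_smoothed[js, , drop = FALSE] -
        matrix(S_smoothed[i, ], k, ncol(S_smoothed), byrow = TRUE)
      cosv <- vapply(seq_len(k), function(r) cosine(Vs[i, ], alldisp[r, ]),
                     numeric(1))
      w <- exp(cosv - max(cosv)); w <- w / sum(w)
      tc <- c(tc, 2 * cosine(w, as.numeric(hit)) - 1)
    }
    if (!used) ve_warn("transition %s>%s has no boundary cells; skipped",
                       from, to)
  }
  if (!any_boundary) ve_stop("no-boundaries", "no usable transitions")
  # length accuracy: velocity magnitude vs local displacement magnitude
  vnorm <- sqrt(rowSums(Vs^2))
  dnorm <- vapply(seq_len(n), function(i) {
    js <- nbr[i, ]
    mean(sqrt(rowSums((S_smoothed[js, , drop = FALSE] -
      matrix(S_smoothed[i, ], k, ncol(S_smoothed), byrow = TRUE))^2)))
  }, numeric(1))
  lenacc <- safe_cor(vnorm, dnorm)
  list(cbdir = if (length(cb1)) mean(cb1) else NA_real_,
       cbdir2 = mean(cb2),
       transcosine = mean(tc),
       lenacc = lenacc)
}

#' Score a fit against simulation ground truth
#'
#' Populates every applicable metric: Pearson pseudotime correlation
#' (circular cross-correlation instead on circular topologies), per-cell
#' velocity correlation, and - when labels, transitions and an embedding are
#' available - the boundary metrics.
#'
#' @param ds the dataset the model was fitted on.
#' @param truth a \code{simulation_truth}.
#' @param fit a fitted \code{velode} object (or list with \code{t} and
#'   \code{velocity}).
#' @param topology \code{"linear"} or \code{"circular"}.
#' @param transitions optional transition list for boundary metrics.
#' @param knn_k neighborhood size.
#' @return An \code{evaluation_report} list; serializes to JSON via
#'   \code{jsonlite}.
#' @export
run_benchmark <- function(ds, truth, fit, topology = "linear",
                          transitions = NULL, knn_k = 30L) {
  rep_ <- list(
    pearson_t = pearson_pseudotime(fit$t, truth$t_true),
    circular_xcorr_t = if (topology == "circular")
      circular_cross_correlation(fit$t, truth$t_true) else NA_real_,
    velocity_corr = velocity_correlation(fit$velocity$Vs, truth$Vs_true),
    cbdir = NA_real_, cbdir2 = NA_real_, transcosine = NA_real_,
    lenacc = NA_real_
  )
  if (!is.null(transitions) && !is.null(ds$cell_labels)) {
    bm <- boundary_metrics(fit$velocity$Vs, ds$S, ds$embedding,
                           ds$cell_labels, transitions, knn_k)
    rep_[c("cbdir", "cbdir2", "transcosine", "lenacc")] <-
      bm[c("cbdir", "cbdir2", "transcosine", "lenacc")]
  }
  structure(rep_, class = "evaluation_report")
}
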