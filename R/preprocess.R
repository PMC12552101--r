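#' Preprocessing configuration
#'
#' @param n_top_genes number of most-variable genes to keep (by spliced
#'   dispersion after normalization). Default 2000, the usual convention for
#'   velocity analyses.
#' @param knn_k neighborhood size for moment smoothing, counting the cell
#'   itself (so \code{knn_k = 1} leaves expression unsmoothed).
#' @param normalize per-cell size-factor normalization of S and U to the
#'   median layer total. Turn off for data without library-size variation
#'   (e.g. simulated abundances).
#' @param log1p_modality_O normalize and log1p-transform the second modality.
#' @param n_pcs number of principal components for the smoothing KNN graph.
#' @return A \code{preprocess_config} list.
#' @export
preprocess_config <- function(n_top_genes = 2000, knn_k = 30,
                              normalize = TRUE, log1p_modality_O = TRUE,
                              n_pcs = 30) {
  stopifnot(n_top_genes >= 2, knn_k >= 1, n_pcs >= 1)
  structure(list(n_top_genes = as.integer(n_top_genes),
                 knn_k = as.integer(knn_k),
                 normalize = isTRUE(normalize),
                 log1p_modality_O = isTRUE(log1p_modality_O),
                 n_pcs = as.integer(n_pcs)),
            class = "preprocess_config")
}

size_factor_normalize <- function(M) {
  totals <- rowSums(M)
  totals[totals == 0] <- 1
  target <- stats::median(totals)
  M * (target / totals)
}

# k-nearest-neighbour index matrix (n x k), neighborhoods include the cell
# itself; built on Euclidean distance over principal components of
# log1p-transformed normalized spliced expression
knn_index <- function(Slog, k, n_pcs) {
  n <- nrow(Slog)
  n_pcs <- min(n_pcs, ncol(Slog), n - 1L)
  pcs <- stats::prcomp(Slog, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  D <- as.matrix(stats::dist(pcs))
  res <- vapply(seq_len(n), function(i) order(D[i, ])[seq_len(k)], integer(k))
  if (k == 1L) matrix(res, n, 1L) else t(res)
}

knn_smooth <- function(M, idx) {
  k <- ncol(idx)
  out <- matrix(0, nrow(M), ncol(M))
  for (j in seq_len(k)) out <- out + M[idx[, j], , drop = FALSE]
  out / k
}

#' Standard preprocessing for velocity modelling
#'
#' Size-factor normalization of S and U per cell, restriction to the most
#' variable genes (spliced dispersion = variance/mean), and KNN smoothing of
#' both layers to first-order moments. The KNN graph is built on principal
#' components of log1p spliced expression only (not a joint S/U graph). The
#' optional modality O is normalized and log1p-transformed. Deterministic
#' given the configuration.
#'
#' @param ds an \code{\link{omics_dataset}}.
#' @param cfg a \code{\link{preprocess_config}}.
#' @return A preprocessed \code{\link{omics_dataset}}.
#' @export
preprocess_dataset <- function(ds, cfg = preprocess_config()) {
  stopifnot(inherits(ds, "omics_dataset"))
  n <- nrow(ds$S); p <- ncol(ds$S)
  if (cfg$knn_k >= n)
    ve_stop("knn-too-large", "knn_k = %d but only %d cells", cfg$knn_k, n)
  S <- ds$S; U <- ds$U
  if (cfg$normalize) {
    S <- size_factor_normalize(S)
    U <- size_factor_normalize(U)
  }
  keep <- seq_len(p)
  if (cfg$n_top_genes > p) {
    ve_warn("n_top_genes = %d exceeds the %d available genes; keeping all",
            cfg$n_top_genes, p)
  } else if (cfg$n_top_genes < p) {
    mu <- colMeans(S)
    v <- apply(S, 2L, stats::var)
    disp <- ifelse(mu > 0, v / mu, 0)
    keep <- sort(order(disp, decreasing = TRUE)[seq_len(cfg$n_top_genes)])
  }
  S <- S[, keep, drop = FALSE]
  U <- U[, keep, drop = FALSE]
  idx <- knn_index(log1p(S), cfg$knn_k, cfg$n_pcs)
  S <- knn_smooth(S, idx)
  U <- knn_smooth(U, idx)
  O <- ds$O
  if (!is.null(O) && cfg$log1p_modality_O)
    O <- log1p(size_factor_normalize(O))
  out <- omics_dataset(S, U, O = O, cell_ids = ds$cell_ids,
                       gene_ids = ds$gene_ids[keep],
                       cell_labels = ds$cell_labels,
                       embedding = ds$embedding)
  attr(out, "preprocessed") <- TRUE
  attr(out, "knn_index") <- idx
  out
}
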