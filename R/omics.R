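#' Construct an aligned spliced/unspliced (multi-omic) dataset
#'
#' Container for the matrices the model consumes: spliced counts/abundances
#' \code{S}, unspliced \code{U} (cells x genes, identical ordering), and an
#' optional second-modality matrix \code{O} (cells x features, e.g. chromatin
#' accessibility) aligned on the same cells.
#'
#' @param S cell x gene non-negative matrix of spliced expression.
#' @param U cell x gene non-negative matrix of unspliced expression, same
#'   dimensions and ordering as \code{S}.
#' @param O optional cell x feature non-negative matrix of a second modality.
#' @param cell_ids,gene_ids character identifiers; defaults are generated.
#' @param cell_labels optional character vector of per-cell labels
#'   (e.g. cell types), length \code{nrow(S)}.
#' @param embedding optional n x 2 matrix (e.g. a UMAP) used by
#'   embedding-space metrics; never computed by this package.
#' @return An object of class \code{omics_dataset}.
#' @export
omics_dataset <- function(S, U, O = NULL, cell_ids = NULL, gene_ids = NULL,
                          cell_labels = NULL, embedding = NULL) {
  S <- as.matrix(S); U <- as.matrix(U)
  if (nrow(S) == 0L || ncol(S) == 0L)
    ve_stop("empty-dataset", "dataset has %d cells and %d genes", nrow(S), ncol(S))
  if (!all(dim(S) == dim(U)))
    ve_stop("shape-mismatch", "S is %dx%d but U is %dx%d",
            nrow(S), ncol(S), nrow(U), ncol(U))
  if (min(S) < 0 || min(U) < 0)
    ve_stop("negative-values", "S and U must be non-negative")
  n <- nrow(S); p <- ncol(S)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(p))
  stopifnot(length(cell_ids) == n, length(gene_ids) == p)
  if (!is.null(O)) {
    O <- as.matrix(O)
    if (nrow(O) != n)
      ve_stop("shape-mismatch", "O has %d rows but dataset has %d cells",
              nrow(O), n)
    if (min(O) < 0) ve_stop("negative-values", "O must be non-negative")
  }
  if (!is.null(cell_labels)) {
    cell_labels <- as.character(cell_labels)
    stopifnot(length(cell_labels) == n)
  }
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    stopifnot(nrow(embedding) == n, ncol(embedding) == 2L)
  }
  dimnames(S) <- dimnames(U) <- list(cell_ids, gene_ids)
  structure(list(S = S, U = U, O = O, cell_ids = cell_ids,
                 gene_ids = gene_ids, cell_labels = cell_labels,
                 embedding = embedding),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("omics_dataset: %d cells x %d genes", nrow(x$S), ncol(x$S)))
  if (!is.null(x$O)) cat(sprintf(" + modality (%d features)", ncol(x$O)))
  if (!is.null(x$cell_labels))
    cat(sprintf("; %d cell labels", length(unique(x$cell_labels))))
  cat("\n")
  invisible(x)
}

#' @export
dim.omics_dataset <- function(x) dim(x$S)

#' Concatenated feature matrix X = (S, U, O)
#'
#' Model input of width m = 2p (+h when a second modality is present).
#' @param ds an \code{omics_dataset}.
#' @return n x m numeric matrix.
#' @export
feature_matrix <- function(ds) {
  X <- cbind(ds$S, ds$U)
  if (!is.null(ds$O)) X <- cbind(X, ds$O)
  unname(X)
}

# subset cells, keeping all aligned fields consistent
subset_cells <- function(ds, idx) {
  omics_dataset(ds$S[idx, , drop = FALSE], ds$U[idx, , drop = FALSE],
                O = if (is.null(ds$O)) NULL else ds$O[idx, , drop = FALSE],
                cell_ids = ds$cell_ids[idx], gene_ids = ds$gene_ids,
                cell_labels = if (is.null(ds$cell_labels)) NULL else ds$cell_labels[idx],
                embedding = if (is.null(ds$embedding)) NULL else ds$embedding[idx, , drop = FALSE])
}
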