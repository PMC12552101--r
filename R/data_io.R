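#' Read a spliced/unspliced dataset from disk
#'
#' Supported formats: \code{"mtx_dir"} (a directory of MatrixMarket files,
#' CellRanger orientation genes x cells on disk, transposed on read),
#' \code{"h5ad"} (AnnData: X = spliced, layers \code{"spliced"} and
#' \code{"unspliced"}, optional \code{obsm["X_emb"]}, \code{obs["cell_type"]},
#' \code{obsm["X_modality"]}) and \code{"loom"} (layers
#' \code{"spliced"}/\code{"unspliced"}). HDF5-backed formats are read through
#' a bundled Python bridge (anndata/h5py), since the computation itself is
#' pure R.
#'
#' An \code{mtx_dir} contains \code{spliced.mtx}, \code{unspliced.mtx},
#' \code{genes.tsv}, \code{barcodes.tsv} and optionally \code{modality.mtx}
#' with \code{features.tsv}, \code{labels.tsv} (one label per cell) and
#' \code{embedding.tsv} (two tab-separated columns per cell).
#'
#' @param path file (h5ad/loom) or directory (mtx_dir).
#' @param format one of \code{"h5ad"}, \code{"loom"}, \code{"mtx_dir"};
#'   guessed from the path when \code{NULL}.
#' @return An \code{\link{omics_dataset}}.
#' @export
read_dataset <- function(path, format = NULL) {
  format <- format %||% guess_format(path)
  switch(format,
    mtx_dir = read_mtx_dir(path),
    h5ad = ,
    loom = read_via_bridge(path, format),
    ve_stop("unknown-format", "unsupported format '%s'", format))
}

#' Write a dataset to disk
#'
#' Round-trips through \code{\link{read_dataset}} for every supported format.
#' @param ds an \code{\link{omics_dataset}}.
#' @inheritParams read_dataset
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(ds, path, format = NULL) {
  stopifnot(inherits(ds, "omics_dataset"))
  format <- format %||% guess_format(path)
  switch(format,
    mtx_dir = write_mtx_dir(ds, path),
    h5ad = ,
    loom = write_via_bridge(ds, path, format),
    ve_stop("unknown-format", "unsupported format '%s'", format))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path) {
  if (grepl("\\.h5ad$", path)) "h5ad"
  else if (grepl("\\.loom$", path)) "loom"
  else "mtx_dir"
}

read_mtx_layer <- function(dir, name, required = TRUE) {
  f <- file.path(dir, paste0(name, ".mtx"))
  if (!file.exists(f)) {
    if (required) ve_stop("layer-missing", "%s", name)
    return(NULL)
  }
  # disk orientation is genes x cells; transpose to cells x genes
  t(as.matrix(Matrix::readMM(f)))
}

read_mtx_dir <- function(dir) {
  if (!dir.exists(dir)) ve_stop("io", "directory '%s' does not exist", dir)
  S <- read_mtx_layer(dir, "spliced")
  U <- read_mtx_layer(dir, "unspliced")
  if (!all(dim(S) == dim(U)))
    ve_stop("shape-mismatch", "spliced is %dx%d, unspliced is %dx%d",
            nrow(S), ncol(S), nrow(U), ncol(U))
  genes <- read_tsv_col(file.path(dir, "genes.tsv"))
  cells <- read_tsv_col(file.path(dir, "barcodes.tsv"))
  O <- read_mtx_layer(dir, "modality", required = FALSE)
  labels <- if (file.exists(file.path(dir, "labels.tsv")))
    read_tsv_col(file.path(dir, "labels.tsv")) else NULL
  emb <- if (file.exists(file.path(dir, "embedding.tsv")))
    as.matrix(utils::read.table(file.path(dir, "embedding.tsv"), sep = "\t"))
  else NULL
  omics_dataset(S, U, O = O, cell_ids = cells, gene_ids = genes,
                cell_labels = labels, embedding = emb)
}

read_tsv_col <- function(f) {
  if (!file.exists(f)) ve_stop("io", "missing file '%s'", f)
  utils::read.table(f, sep = "\t", stringsAsFactors = FALSE)[[1]]
}

write_mtx_layer <- function(M, dir, name) {
  # genes x cells on disk (CellRanger convention)
  Matrix::writeMM(Matrix::Matrix(t(M), sparse = TRUE),
                  file.path(dir, paste0(name, ".mtx")))
}

write_mtx_dir <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx_layer(ds$S, dir, "spliced")
  write_mtx_layer(ds$U, dir, "unspliced")
  writeLines(ds$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(ds$cell_ids, file.path(dir, "barcodes.tsv"))
  if (!is.null(ds$O)) {
    write_mtx_layer(ds$O, dir, "modality")
    writeLines(colnames(ds$O) %||% sprintf("feat_%d", seq_len(ncol(ds$O))),
               file.path(dir, "features.tsv"))
  }
  if (!is.null(ds$cell_labels))
    writeLines(ds$cell_labels, file.path(dir, "labels.tsv"))
  if (!is.null(ds$embedding))
    utils::write.table(ds$embedding, file.path(dir, "embedding.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

bridge_script <- function() {
  f <- system.file("py", "h5_bridge.py", package = "velode")
  if (!nzchar(f)) f <- file.path("inst", "py", "h5_bridge.py")
  f
}

run_bridge <- function(args) {
  py <- Sys.which("python")
  if (!nzchar(py)) ve_stop("io", "python interpreter not found on PATH")
  out <- suppressWarnings(system2(py, c(bridge_script(), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    msg <- paste(out, collapse = "\n")
    if (grepl("layer-missing", msg))
      ve_stop("layer-missing", "%s", sub(".*layer-missing: *", "", msg))
    if (grepl("shape-mismatch", msg)) ve_stop("shape-mismatch", "%s", msg)
    ve_stop("io", "bridge failed: %s", msg)
  }
  invisible(out)
}

read_via_bridge <- function(path, format) {
  if (!file.exists(path)) ve_stop("io", "file '%s' does not exist", path)
  tmp <- tempfile("velode_exchange_")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  run_bridge(c("to_exchange", path, tmp))
  read_mtx_dir(tmp)
}

write_via_bridge <- function(ds, path, format) {
  tmp <- tempfile("velode_exchange_")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  write_mtx_dir(ds, tmp)
  run_bridge(c("from_exchange", tmp, path))
  invisible(path)
}
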