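#' Read a count matrix into a count dataset
#'
#' Supported formats: `"mtx"` (Matrix Market coordinate file with
#' sibling `genes.tsv` / `barcodes.tsv` and optional `labels.tsv` /
#' `batches.tsv` written by [write_counts()]), `"csv"` (cells x genes
#' with a header of gene names and cell names in the first column), and
#' `"10x-dir"` (a directory holding `matrix.mtx`, `features.tsv`,
#' `barcodes.tsv` in the genes-x-cells orientation).
#'
#' The returned matrix always has cells as rows; use `transpose = TRUE`
#' if an mtx/csv file is stored genes x cells. Negative or fractional
#' entries are rejected with a diagnostic. All-zero genes are dropped.
#'
#' @param path File (mtx/csv) or directory (10x-dir).
#' @param format One of `"mtx"`, `"csv"`, `"10x-dir"`.
#' @param transpose Flip the on-disk orientation (ignored for 10x-dir,
#'   which is always genes x cells on disk).
#' @param batch Optional path to a one-label-per-line batch TSV
#'   overriding any sibling file.
#' @param verbose Report dropped genes.
#' @return A [count_dataset()].
#' @export
read_counts <- function(path, format = c("mtx", "csv", "10x-dir"),
                        transpose = FALSE, batch = NULL, verbose = FALSE) {
  format <- match.arg(format)
  read_col <- function(f) if (file.exists(f))
    utils::read.table(f, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1]] else NULL

  if (format == "10x-dir") {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop(sprintf("no matrix.mtx under '%s'", path))
    m <- as.matrix(Matrix::readMM(mtx))
    .check_entries(m, mtx)
    genes <- read_col(file.path(path, "features.tsv")) %||%
      read_col(file.path(path, "genes.tsv"))
    cells <- read_col(file.path(path, "barcodes.tsv"))
    m <- t(m)                                    # 10x stores genes x cells
    return(count_dataset(m, gene_names = genes, cell_names = cells,
                         batch = if (!is.null(batch)) read_col(batch),
                         verbose = verbose))
  }

  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    .check_entries(m, path)
    if (transpose) m <- t(m)
    dir <- dirname(path)
    genes <- read_col(file.path(dir, "genes.tsv"))
    cells <- read_col(file.path(dir, "barcodes.tsv"))
    b <- if (!is.null(batch)) read_col(batch) else
      read_col(file.path(dir, "batches.tsv"))
    labels <- read_col(file.path(dir, "labels.tsv"))
    return(count_dataset(m, gene_names = genes, cell_names = cells,
                         batch = b, true_labels = labels,
                         verbose = verbose))
  }

  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  .check_entries(m, path)
  if (transpose) m <- t(m)
  b <- if (!is.null(batch)) read_col(batch)
  count_dataset(m, gene_names = colnames(m), cell_names = rownames(m),
                batch = b, verbose = verbose)
}

.check_entries <- function(m, path) {
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("%s: negative entry at row %d, column %d",
                 path, bad[1], bad[2]))
  }
  if (any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: fractional entry at row %d, column %d",
                 path, bad[1], bad[2]))
  }
  invisible(m)
}

#' Write a count dataset as Matrix Market plus sidecar TSVs
#'
#' Writes `counts.mtx` (cells x genes, integer coordinate format),
#' `genes.tsv`, `barcodes.tsv`, and — when present — `batches.tsv` and
#' `labels.tsv`, into `dir`.
#'
#' @param dataset A [count_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(dataset, dir) {
  stopifnot(inherits(dataset, "count_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # coordinate integer dialect, 1-based (Matrix::writeMM would emit "real")
  m <- dataset$counts
  nz <- which(m != 0, arr.ind = TRUE)
  con <- file(file.path(dir, "counts.mtx"), "w")
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), nrow(nz)), con)
  if (nrow(nz))
    writeLines(sprintf("%d %d %d", nz[, 1], nz[, 2],
                       as.integer(m[nz])), con)
  close(con)
  writeLines(dataset$gene_names, file.path(dir, "genes.tsv"))
  writeLines(dataset$cell_names, file.path(dir, "barcodes.tsv"))
  if (nlevels(dataset$batch) > 1 || !is.null(dataset$true_labels))
    writeLines(as.character(dataset$batch), file.path(dir, "batches.tsv"))
  if (!is.null(dataset$true_labels))
    writeLines(as.character(dataset$true_labels),
               file.path(dir, "labels.tsv"))
  invisible(dir)
}
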