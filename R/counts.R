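#' Assemble a cell-by-gene count dataset
#'
#' The canonical data container used throughout the package: a dense
#' non-negative integer matrix with cells as rows, an optional per-cell
#' batch annotation and optional ground-truth group labels (from
#' simulations). Genes with all-zero counts are dropped at construction
#' time because their dispersion is undefined under the ZINB observation
#' model; the number removed is reported.
#'
#' @param counts Numeric matrix (or Matrix sparse matrix), cells x genes,
#'   non-negative integers.
#' @param batch Per-cell batch labels (character/factor, length = n cells).
#'   Defaults to a single batch.
#' @param gene_names,cell_names Optional dimension names; default to the
#'   matrix dimnames or generated names.
#' @param true_labels Optional per-cell ground-truth group labels.
#' @param verbose Report dropped all-zero genes.
#' @return An object of class `count_dataset` with elements `counts`,
#'   `batch` (factor), `gene_names`, `cell_names`, `true_labels`.
#' @export
count_dataset <- function(counts, batch = NULL, gene_names = NULL,
                          cell_names = NULL, true_labels = NULL,
                          verbose = FALSE) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at cell %d, gene %d", bad[1], bad[2]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at cell %d, gene %d", bad[1], bad[2]))
  }
  n <- nrow(counts)
  gene_names <- gene_names %||% colnames(counts) %||%
    sprintf("gene%d", seq_len(ncol(counts)))
  cell_names <- cell_names %||% rownames(counts) %||%
    sprintf("cell%d", seq_len(n))
  if (is.null(batch)) batch <- rep("batch1", n)
  if (length(batch) != n) stop("batch must have one label per cell")
  batch <- factor(as.character(batch))
  if (!is.null(true_labels)) {
    if (length(true_labels) != n) stop("true_labels must have one label per cell")
    true_labels <- factor(as.character(true_labels))
  }
  keep <- colSums(counts) > 0
  if (any(!keep)) {
    msg(sprintf("dropping %d all-zero gene(s)", sum(!keep)), verbose = verbose)
    counts <- counts[, keep, drop = FALSE]
    gene_names <- gene_names[keep]
  }
  dimnames(counts) <- NULL
  structure(
    list(counts = counts, batch = batch, gene_names = gene_names,
         cell_names = cell_names, true_labels = true_labels),
    class = "count_dataset"
  )
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: %d cells x %d genes, %d batch(es)%s\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$batch),
              if (!is.null(x$true_labels))
                sprintf(", %d true groups", nlevels(x$true_labels)) else ""))
  invisible(x)
}

#' @export
dim.count_dataset <- function(x) dim(x$counts)

#' Subset cells of a count dataset
#'
#' @param dataset A `count_dataset`.
#' @param cells Integer or logical index over cells.
#' @return A `count_dataset` restricted to the selected cells. Gene
#'   filtering is not re-applied, so gene indices stay aligned with the
#'   parent dataset.
#' @export
subset_cells <- function(dataset, cells) {
  stopifnot(inherits(dataset, "count_dataset"))
  out <- dataset
  out$counts <- dataset$counts[cells, , drop = FALSE]
  out$batch <- factor(dataset$batch[cells], levels = levels(dataset$batch))
  out$cell_names <- dataset$cell_names[cells]
  if (!is.null(dataset$true_labels))
    out$true_labels <- dataset$true_labels[cells]
  out
}
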