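#' Built-in cluster assignment from mixture responsibilities
#'
#' Encodes each cell deterministically as the posterior mean mu_z and
#' assigns it to the mixture component with the largest responsibility
#' q(c | mu_z). Ties are broken toward the lowest component index.
#' Labels are relabeled to consecutive integers 1..K over non-empty
#' clusters.
#'
#' @param state A fitted `zinbmix_fit`.
#' @param dataset The [count_dataset()] to label.
#' @return A `clustering_result`: `labels` (integer vector), `method`,
#'   `responsibilities` (n x C matrix), `cell_names`.
#' @export
assign_builtin <- function(state, dataset) {
  stopifnot(inherits(state, "zinbmix_fit"))
  mu_z <- encode(state, dataset)$mu_z
  q <- gmm_responsibilities(mu_z, state$prior)
  raw <- max.col(q, ties.method = "first")
  labels <- as.integer(factor(raw, levels = sort(unique(raw))))
  structure(list(labels = labels, method = "builtin",
                 responsibilities = q, cell_names = dataset$cell_names),
            class = "clustering_result")
}

# k-nearest-neighbour index matrix (self excluded) from a latent matrix.
.knn_index <- function(latent, k) {
  n <- nrow(latent)
  if (k >= n) stop(sprintf("n_neighbors = %d requires more than %d cells", k, n))
  dm <- as.matrix(stats::dist(latent))
  t(apply(dm, 1L, function(r) order(r)[2:(k + 1)]))
}

# Shared-nearest-neighbour (Jaccard) weighted graph from a KNN index.
.snn_graph <- function(nn) {
  n <- nrow(nn); k <- ncol(nn)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)              # counts of shared neighbours
  mask <- adj + Matrix::t(adj)                   # union of KNN relations
  w <- shared * (mask > 0)
  w <- methods::as(w, "TsparseMatrix")
  keep <- w@i < w@j
  i <- w@i[keep] + 1L; j <- w@j[keep] + 1L
  jac <- w@x[keep] / (2 * k - w@x[keep])
  g <- igraph::graph_from_edgelist(cbind(i, j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- jac
  g
}

#' Louvain clustering of the latent encodings
#'
#' Builds a KNN graph (Euclidean distances between the deterministic
#' encodings mu_z), weights edges by shared-neighbour (Jaccard) overlap,
#' and runs Louvain modularity optimization. The result depends only on
#' the encodings, `n_neighbors`, `resolution` and `seed`.
#'
#' @param state A fitted `zinbmix_fit`.
#' @param dataset The [count_dataset()] to label.
#' @param n_neighbors Neighbours per cell in the KNN graph (>= 2).
#' @param resolution Louvain resolution parameter.
#' @param seed Seed for the community search (deterministic given seed).
#' @return A `clustering_result` with `labels`, `method = "louvain"` and
#'   the graph parameters.
#' @export
assign_louvain <- function(state, dataset, n_neighbors = 15,
                           resolution = 0.5, seed = 1) {
  stopifnot(inherits(state, "zinbmix_fit"), n_neighbors >= 2)
  mu_z <- encode(state, dataset)$mu_z
  latent_louvain(mu_z, n_neighbors = n_neighbors, resolution = resolution,
                 seed = seed, cell_names = dataset$cell_names)
}

#' Louvain community detection on an arbitrary embedding
#'
#' The graph-clustering backend of [assign_louvain()], usable on any
#' numeric embedding.
#'
#' @param latent n x d numeric matrix.
#' @param n_neighbors,resolution,seed See [assign_louvain()].
#' @param cell_names Optional names carried into the result.
#' @return A `clustering_result`.
#' @export
latent_louvain <- function(latent, n_neighbors = 15, resolution = 0.5,
                           seed = 1, cell_names = NULL) {
  stopifnot(n_neighbors >= 2)
  nn <- .knn_index(latent, n_neighbors)
  g <- .snn_graph(nn)
  comm <- with_local_seed(seed,
                          igraph::cluster_louvain(g, resolution = resolution))
  raw <- igraph::membership(comm)
  labels <- as.integer(factor(raw, levels = sort(unique(raw))))
  structure(list(labels = labels, method = "louvain",
                 graph_params = list(n_neighbors = n_neighbors,
                                     resolution = resolution, seed = seed),
                 cell_names = cell_names),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result (%s): %d cells in %d cluster(s)\n",
              x$method, length(x$labels), length(unique(x$labels))))
  invisible(x)
}

#' Write cluster labels as a two-column TSV
#'
#' @param result A `clustering_result`.
#' @param path Output file (columns: cell, label).
#' @export
write_labels <- function(result, path) {
  cells <- result$cell_names %||% sprintf("cell%d", seq_along(result$labels))
  utils::write.table(data.frame(cell = cells, label = result$labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
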