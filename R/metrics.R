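#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions.
#' With a, b, c, d the numbers of object pairs that are together in both
#' partitions, together only in the first, together only in the second,
#' and separated in both,
#' \deqn{ARI = \frac{\binom n2 (a+d) - [(a+b)(a+c) + (c+d)(b+d)]}
#'   {\binom n2^2 - [(a+b)(a+c)+(c+d)(b+d)]}.}
#'
#' @param u,v Two label vectors of equal length (any atomic type).
#' @return ARI in `[-1, 1]`; 1 for identical partitions, ~0 at chance.
#' @export
ari <- function(u, v) {
  if (length(u) != length(v)) stop("partitions must have equal length")
  n <- length(u)
  ct <- table(u, v)
  ch2 <- function(x) x * (x - 1) / 2
  a <- sum(ch2(ct))                         # together in both
  ab <- sum(ch2(rowSums(ct)))               # together in u
  ac <- sum(ch2(colSums(ct)))               # together in v
  tp <- ch2(n)                              # total pairs, C(n, 2)
  b <- ab - a; c <- ac - a
  d <- tp - a - b - c
  brack <- (a + b) * (a + c) + (c + d) * (b + d)
  denom <- tp^2 - brack
  if (denom == 0) return(1)                 # degenerate: no chance variation
  (tp * (a + d) - brack) / denom
}

#' Normalized mutual information
#'
#' I(U, V) / max(H(U), H(V)) with mutual information and entropies taken
#' over the joint cluster-overlap counts; the convention 0 log 0 = 0
#' applies. Two identical single-cluster partitions score 1.
#'
#' @inheritParams ari
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(u, v) {
  if (length(u) != length(v)) stop("partitions must have equal length")
  n <- length(u)
  ct <- as.matrix(table(u, v))
  pu <- rowSums(ct) / n
  pv <- colSums(ct) / n
  hu <- -sum(ifelse(pu > 0, pu * log(pu), 0))
  hv <- -sum(ifelse(pv > 0, pv * log(pv), 0))
  if (hu == 0 && hv == 0) return(1)        # both single-cluster: identical
  pj <- ct / n
  E <- outer(pu, pv)
  i_uv <- sum(ifelse(pj > 0, pj * log(pj / E), 0))
  i_uv / max(hu, hv)
}

#' KL divergence of batch mixing in a latent space
#'
#' Measures how well batches mix locally: repeatedly samples query cells,
#' takes each query's k nearest neighbours (Euclidean, self excluded),
#' forms the regional batch proportions q_b, and computes
#' sum_b q_b log(q_b / p_b) against the global proportions p_b (with
#' 0 log 0 = 0). Regional divergences are averaged within an iteration
#' and across iterations. Zero means locally perfect mixing; larger
#' values mean batch-segregated neighbourhoods.
#'
#' @param latent n x d matrix of latent encodings.
#' @param batch Per-cell batch labels (at least 2 distinct, all present).
#' @param k Neighbours per region (default 50; must be >= 2).
#' @param n_regions Query cells sampled per iteration (default 50).
#' @param n_iterations Repeats averaged (default 100).
#' @param seed Seed for the query sampling.
#' @return Non-negative scalar.
#' @export
batch_mixing_kl <- function(latent, batch, k = 50, n_regions = 50,
                            n_iterations = 100, seed = 1) {
  if (!is.matrix(latent)) latent <- as.matrix(latent)
  n <- nrow(latent)
  batch <- factor(as.character(batch))
  if (length(batch) != n) stop("batch must have one label per cell")
  if (nlevels(batch) < 2) stop("need at least 2 batches")
  if (any(table(batch) == 0)) stop("a batch level is absent from the data")
  if (k < 2) stop("region size k must be at least 2")
  if (n <= k) stop("need more cells than neighbours")
  p <- as.numeric(table(batch)) / n
  B <- nlevels(batch)
  nn <- .knn_index(latent, k)
  bi <- as.integer(batch)
  # regional KL for every cell, computed once; iterations just resample cells
  region_kl <- vapply(seq_len(n), function(i) {
    q <- tabulate(bi[nn[i, ]], B) / k
    pos <- q > 0
    sum(q[pos] * (log(q[pos]) - log(p[pos])))
  }, 0)
  with_local_seed(seed, {
    mean(vapply(seq_len(n_iterations), function(it) {
      mean(region_kl[sample.int(n, n_regions)])
    }, 0))
  })
}
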