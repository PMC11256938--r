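#' Gaussian-mixture latent prior
#'
#' The heterogeneity model for the latent cell representation z: a mixture
#' of C Gaussians with identity covariances,
#' p(z) = sum_c pi_c N(z; mu_c, I). Only the weights and means are free;
#' the covariance is fixed at the identity by construction and no
#' covariance field exists.
#'
#' @param pi Mixture weights, length C, positive, summing to 1.
#' @param mu C x d matrix of component means (a vector is taken as one
#'   mean per row for d = 1 when `pi` has matching length, otherwise as a
#'   single mean).
#' @return Object of class `gmm_prior` with fields `C`, `pi`, `mu`.
#' @export
gmm_prior <- function(pi, mu) {
  if (!is.matrix(mu)) {
    mu <- if (length(pi) == 1L) matrix(mu, nrow = 1L) else matrix(mu, ncol = 1L)
  }
  pi <- as.numeric(pi)
  if (length(pi) != nrow(mu)) stop("length(pi) must equal nrow(mu)")
  if (any(pi <= 0)) stop("all mixture weights must be > 0")
  if (abs(sum(pi) - 1) > 1e-8) stop("mixture weights must sum to 1")
  structure(list(C = length(pi), pi = pi, mu = mu, d = ncol(mu)),
            class = "gmm_prior")
}

#' @export
print.gmm_prior <- function(x, ...) {
  cat(sprintf("gmm_prior: C = %d components in %d dimensions (identity covariances)\n",
              x$C, x$d))
  invisible(x)
}

#' Per-batch empirical prior for the log scaling factor
#'
#' The scaling factor t captures capture efficiency and sequencing depth;
#' log t is modelled as Gaussian with per-batch prior parameters set to
#' the empirical mean and variance of the log library size
#' log(sum_g x_ng) within each batch.
#'
#' @param dataset A [count_dataset()].
#' @param var_floor Lower bound applied to the per-batch variance so that
#'   single-cell batches or constant library sizes keep a proper prior.
#' @return Object of class `library_prior` with per-batch `mu_bar` and
#'   `sigma_bar_sq`, named by batch level.
#' @details The variance is the population (1/N) variance of the
#'   per-cell log library sizes within the batch.
#' @export
compute_library_prior <- function(dataset, var_floor = 1e-4) {
  stopifnot(inherits(dataset, "count_dataset"))
  totals <- rowSums(dataset$counts)
  if (any(totals <= 0)) {
    bad <- which(totals <= 0)[1]
    stop(sprintf("cell '%s' has zero total count; cannot form log-library prior",
                 dataset$cell_names[bad]))
  }
  logl <- log(totals)
  levs <- levels(dataset$batch)
  mu_bar <- vapply(levs, function(b) mean(logl[dataset$batch == b]), 0)
  sigma_bar_sq <- vapply(levs, function(b) {
    v <- logl[dataset$batch == b]
    mean((v - mean(v))^2)  # population variance
  }, 0)
  sigma_bar_sq <- pmax(sigma_bar_sq, var_floor)
  structure(list(mu_bar = mu_bar, sigma_bar_sq = sigma_bar_sq,
                 batches = levs),
            class = "library_prior")
}

#' @export
print.library_prior <- function(x, ...) {
  cat("library_prior (log-library Gaussian, per batch):\n")
  print(data.frame(batch = x$batches, mu_bar = x$mu_bar,
                   sigma_bar_sq = x$sigma_bar_sq, row.names = NULL))
  invisible(x)
}
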