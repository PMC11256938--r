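#' Zero-inflated negative binomial log probability mass
#'
#' Log-density of the count observation model: with probability `alpha`
#' the entry is a technical dropout (a point mass at zero), otherwise the
#' count follows a negative binomial arising as a Gamma-Poisson mixture
#' with mean `mu` and inverse dispersion `theta`:
#' \deqn{p(x) = \alpha\,1\{x=0\} + (1-\alpha)\,NB(x;\mu,\theta).}
#'
#' All arguments are recycled to a common length. The computation is done
#' in log space and is stable at x = 0 and for large `theta`.
#'
#' @param x Non-negative integer counts.
#' @param mu Positive NB means.
#' @param theta Positive inverse dispersions (NB size).
#' @param alpha Dropout probabilities in `[0, 1)`; `alpha = 1` is allowed
#'   and yields `-Inf` for x > 0 and 0 for x = 0.
#' @return Log probabilities, same length as the recycled inputs.
#' @export
zinb_log_pmf <- function(x, mu, theta, alpha = 0) {
  n <- max(length(x), length(mu), length(theta), length(alpha))
  x <- rep_len(x, n); mu <- rep_len(mu, n)
  theta <- rep_len(theta, n); alpha <- rep_len(alpha, n)
  if (any(x < 0) || any(x != round(x))) stop("x must be non-negative integers")
  if (any(mu <= 0) || any(theta <= 0)) stop("mu and theta must be > 0")
  if (any(alpha < 0) || any(alpha > 1)) stop("alpha must lie in [0, 1]")

  nb <- stats::dnbinom(x, size = theta, mu = mu, log = TRUE)
  out <- numeric(n)
  z <- x == 0
  # x = 0: log(alpha + (1 - alpha) * NB(0)), computed via log-sum-exp
  if (any(z)) {
    la <- ifelse(alpha[z] > 0, log(alpha[z]), -Inf)
    l1a <- ifelse(alpha[z] < 1, log1p(-alpha[z]), -Inf)
    out[z] <- pmax(la, l1a + nb[z]) +
      log1p(exp(-abs(la - (l1a + nb[z]))))
    # guard the pure point-mass / pure NB edges
    out[z][alpha[z] == 0] <- nb[z][alpha[z] == 0]
    out[z][alpha[z] == 1] <- 0
  }
  if (any(!z)) {
    l1a <- ifelse(alpha[!z] < 1, log1p(-alpha[!z]), -Inf)
    out[!z] <- l1a + nb[!z]
  }
  out
}

#' Log-density of the Gaussian-mixture latent prior
#'
#' Evaluates log p(z) = log sum_c pi_c N(z; mu_c, I) by log-sum-exp over
#' components.
#'
#' @param z A length-d vector or an n x d matrix of latent points.
#' @param prior A [gmm_prior()].
#' @return Log-density, one value per row of `z`.
#' @export
gmm_log_density <- function(z, prior) {
  stopifnot(inherits(prior, "gmm_prior"))
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  if (ncol(z) != prior$d)
    stop(sprintf("z has dimension %d but the prior has dimension %d",
                 ncol(z), prior$d))
  lw <- .gmm_logweights(z, prior)          # n x C: log pi_c + log N(z; mu_c, I)
  as.numeric(row_logsumexp(lw))
}

# log pi_c + log N(z; mu_c, I) for every row of z; n x C matrix.
.gmm_logweights <- function(z, prior) {
  d <- prior$d
  sq <- outer(rowSums(z^2), rep(1, prior$C)) -
    2 * z %*% t(prior$mu) +
    outer(rep(1, nrow(z)), rowSums(prior$mu^2))
  sweep(-0.5 * sq, 2L, log(prior$pi), "+") - 0.5 * d * log(2 * pi)
}

#' Mixture responsibilities q(c | z)
#'
#' Posterior component probabilities under the Gaussian-mixture prior,
#' q(c|z) = pi_c N(z; mu_c, I) / sum_c pi_c N(z; mu_c, I), computed as a
#' log-space softmax of log pi_c - ||z - mu_c||^2 / 2 (the shared identity
#' covariance cancels the Gaussian normalizing constant).
#'
#' @inheritParams gmm_log_density
#' @return An n x C matrix with rows on the simplex.
#' @export
gmm_responsibilities <- function(z, prior) {
  stopifnot(inherits(prior, "gmm_prior"))
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  if (ncol(z) != prior$d)
    stop(sprintf("z has dimension %d but the prior has dimension %d",
                 ncol(z), prior$d))
  row_softmax(.gmm_logweights(z, prior))
}

#' KL divergence from the variational scaling-factor posterior to its prior
#'
#' Closed-form KL between two univariate Gaussians on the log scaling
#' factor: q = N(mu_t, sigma_t^2) against the batch's empirical prior
#' N(mu_bar, sigma_bar^2):
#' \deqn{KL = \log(\bar\sigma/\sigma) + (\sigma^2 + (\mu-\bar\mu)^2) /
#'   (2\bar\sigma^2) - 1/2.}
#'
#' @param mu_t,sigma_t Variational mean and standard deviation (vectors ok).
#' @param prior A `library_prior` from [compute_library_prior()].
#' @param batch Batch label(s), recycled against `mu_t`.
#' @return Non-negative KL value(s).
#' @export
kl_library <- function(mu_t, sigma_t, prior, batch) {
  stopifnot(inherits(prior, "library_prior"))
  if (any(sigma_t <= 0)) stop("sigma_t must be > 0")
  batch <- as.character(batch)
  unknown <- setdiff(unique(batch), prior$batches)
  if (length(unknown))
    stop(sprintf("unknown batch label '%s'", unknown[1]))
  i <- match(batch, prior$batches)
  mb <- prior$mu_bar[i]; vb <- prior$sigma_bar_sq[i]
  0.5 * log(vb) - log(sigma_t) + (sigma_t^2 + (mu_t - mb)^2) / (2 * vb) - 0.5
}

#' KL divergence between two categorical distributions
#'
#' sum_c q_c log(q_c / pi_c), with the convention 0 * log 0 = 0. If some
#' q_c > 0 where pi_c = 0 the divergence is `+Inf` (and a warning is
#' emitted).
#'
#' @param q,pi Probability vectors on the simplex (or matrices with one
#'   distribution per row, compared row-wise against the vector `pi`).
#' @return Non-negative value(s).
#' @export
kl_categorical <- function(q, pi) {
  if (is.matrix(q)) {
    return(apply(q, 1L, kl_categorical, pi = pi))
  }
  if (length(q) != length(pi)) stop("q and pi must have equal length")
  if (abs(sum(q) - 1) > 1e-6 || abs(sum(pi) - 1) > 1e-6 ||
      any(q < -1e-12) || any(pi < -1e-12))
    stop("q and pi must be probability vectors")
  pos <- q > 0
  if (any(pos & pi == 0)) {
    warning("q places mass where pi is zero; KL is +Inf")
    return(Inf)
  }
  sum(q[pos] * (log(q[pos]) - log(pi[pos])))
}
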