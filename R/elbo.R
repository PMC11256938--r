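#' Monte Carlo estimator of the mixture-unfolded variational bound
#'
#' Evaluates, from explicit pieces, the per-minibatch estimator used in
#' training: for each cell,
#' \deqn{-KL(q(t|x,s)\,\|\,p(t)) + \frac1L\sum_l\big[\log p(x|z_l,t_l,s)
#'   - \log q(z_l|x,s) - KL(q(c|z_l)\,\|\,p(c)) +
#'   \sum_c q(c|z_l)\log p(z_l|c)\big],}
#' summed over cells. The mixture terms are computed literally from the
#' closed-form responsibilities; analytically they equal the mixture
#' log-density log p(z_l).
#'
#' @param dataset A [count_dataset()] slice (the minibatch).
#' @param posterior A `variational_posterior` for the same cells.
#' @param decoder_out A `decoder_output` (when L = 1) or a list of them,
#'   one per Monte Carlo sample, evaluated at the corresponding draws.
#' @param prior A [gmm_prior()].
#' @param lib_prior A `library_prior`.
#' @param samples A `latent_samples` object holding the draws.
#' @return The scalar estimator value.
#' @export
elbo_estimate <- function(dataset, posterior, decoder_out, prior,
                          lib_prior, samples) {
  stopifnot(inherits(dataset, "count_dataset"),
            inherits(posterior, "variational_posterior"),
            inherits(prior, "gmm_prior"),
            inherits(samples, "latent_samples"))
  L <- length(samples$z)
  if (inherits(decoder_out, "decoder_output")) decoder_out <- list(decoder_out)
  if (length(decoder_out) != L)
    stop("need one decoder output per Monte Carlo sample")
  X <- dataset$counts
  n <- nrow(X)
  kl_t <- kl_library(posterior$mu_t, posterior$sigma_t, lib_prior,
                     dataset$batch)
  logpi <- log(prior$pi)
  acc <- numeric(n)
  for (l in seq_len(L)) {
    z <- samples$z[[l]]; tfac <- samples$t[[l]]
    dec <- decoder_out[[l]]
    MU <- dec$rho * tfac
    A <- stats::qlogis(dec$alpha)
    ll <- rowSums(.zinb_ll_terms(X, MU, dec$theta, A)$ll)
    logq <- rowSums(-0.5 * log(2 * pi) - log(posterior$sigma_z) -
                      (z - posterior$mu_z)^2 / (2 * posterior$sigma_z^2))
    lw <- .gmm_logweights(z, prior)
    q <- row_softmax(lw)
    lognc <- sweep(lw, 2L, logpi, "-")
    qs <- pmax(q, 1e-300)
    mix <- -rowSums(q * (log(qs) - rep(logpi, each = n))) +
      rowSums(q * lognc)
    term <- ll - logq + mix
    if (any(!is.finite(term))) {
      bad <- which(!is.finite(term))[1]
      parts <- c(zinb = ll[bad], logq = logq[bad], mixture = mix[bad])
      stop(sprintf("non-finite ELBO term for cell %d (%s)", bad,
                   paste(names(parts)[!is.finite(parts)], collapse = ", ")))
    }
    acc <- acc + term
  }
  if (any(!is.finite(kl_t))) {
    stop(sprintf("non-finite library KL for cell %d",
                 which(!is.finite(kl_t))[1]))
  }
  sum(-kl_t + acc / L)
}
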