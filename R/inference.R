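#' Training configuration
#'
#' Hyper-parameters of the variational fit. The defaults are the model's
#' standard settings: a 10-dimensional latent space, one Monte Carlo
#' sample per cell, minibatches of 128 cells, at most 400 epochs, and an
#' Adam learning rate of 1e-3.
#'
#' @param latent_dim Dimension d of the latent representation z.
#' @param mc_samples Monte Carlo samples L per cell and step.
#' @param minibatch_size Cells per gradient step.
#' @param max_epochs Maximum training epochs.
#' @param learning_rate Adam step size.
#' @param seed Seed controlling initialization, shuffling and sampling;
#'   the full fit is deterministic given the seed.
#' @param convergence_tol Relative change of the smoothed epoch estimator
#'   below which training stops (checked over a 10-epoch window).
#' @param hidden_dim Hidden-layer width of each of the four networks.
#' @param warmup_epochs Epochs trained under a single standard-normal
#'   prior component before the mixture is initialized by k-means on the
#'   accumulated encodings.
#' @return A `training_config` list.
#' @export
training_config <- function(latent_dim = 10, mc_samples = 1,
                            minibatch_size = 128, max_epochs = 400,
                            learning_rate = 1e-3, seed = 1,
                            convergence_tol = 1e-4, hidden_dim = 128,
                            warmup_epochs = 10, input_dropout = 0.1) {
  stopifnot(latent_dim >= 1, mc_samples >= 1, minibatch_size >= 1,
            max_epochs >= 0, learning_rate >= 0, warmup_epochs >= 0)
  structure(list(latent_dim = as.integer(latent_dim),
                 mc_samples = as.integer(mc_samples),
                 minibatch_size = as.integer(minibatch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 convergence_tol = convergence_tol,
                 hidden_dim = as.integer(hidden_dim),
                 warmup_epochs = as.integer(warmup_epochs),
                 input_dropout = input_dropout),
            class = "training_config")
}

.new_state <- function(dataset, n_components, config) {
  X <- dataset$counts
  G <- ncol(X); B <- nlevels(dataset$batch); d <- config$latent_dim
  xl <- log1p(X)
  depth <- 1e4   # standard depth target for log-normalized expression
  xn <- log1p(X / rowSums(X) * depth)
  std <- list(m = colMeans(xl),
              s = pmax(apply(xl, 2L, stats::sd), 1e-3),
              mn = colMeans(xn),
              sn = pmax(apply(xn, 2L, stats::sd), 1e-3),
              depth = depth)
  params <- .smart_bias_init(.init_params(G, B, d, config$hidden_dim), X,
                             std, dataset$batch)
  bn <- .init_bn_stats(params, std, X, one_hot(dataset$batch))
  prior <- gmm_prior(1, matrix(0, 1, d))   # warm-up / non-mixture prior
  structure(list(
    params = params, prior = prior, n_components = as.integer(n_components),
    lib_prior = compute_library_prior(dataset), std = std,
    config = config, batch_levels = levels(dataset$batch),
    gene_names = dataset$gene_names, n_genes = G,
    bn = bn,
    opt = NULL, elbo_trace = numeric(0), epochs_run = 0L,
    mixture_initialized = n_components == 1L, converged = FALSE,
    em_events = character(0)
  ), class = "zinbmix_fit")
}

#' @export
print.zinbmix_fit <- function(x, ...) {
  cat(sprintf(paste0("zinbmix_fit: %d genes, %d batch level(s), C = %d, ",
                     "d = %d, %d epoch(s) run%s\n"),
              x$n_genes, length(x$batch_levels), x$n_components,
              x$config$latent_dim, x$epochs_run,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

# Validate a dataset slice against a fitted/initialized state and return
# the pieces the forward pass needs.
.state_inputs <- function(state, dataset) {
  if (ncol(dataset$counts) != state$n_genes)
    stop(sprintf("dataset has %d genes but the model was built for %d",
                 ncol(dataset$counts), state$n_genes))
  unknown <- setdiff(levels(droplevels(dataset$batch)), state$batch_levels)
  if (length(unknown))
    stop(sprintf("unseen batch label '%s'", unknown[1]))
  b <- factor(as.character(dataset$batch), levels = state$batch_levels)
  list(X = dataset$counts, Sm = one_hot(b), bidx = as.integer(b))
}

#' Encode cells to their variational posterior parameters
#'
#' Runs the two encoder networks on a dataset (or slice), returning the
#' per-cell Gaussian posterior parameters for the latent representation z
#' and the log scaling factor.
#'
#' @param state A `zinbmix_fit` (from [fit_zinbmix()] or an initialized
#'   state).
#' @param dataset A [count_dataset()] with the same genes and known batch
#'   labels.
#' @return A `variational_posterior`: list with `mu_z`, `sigma_z`
#'   (n x d), `mu_t`, `sigma_t` (length n). All sigma entries are strictly
#'   positive by construction (exponential link with clamped log scale).
#' @export
encode <- function(state, dataset) {
  stopifnot(inherits(state, "zinbmix_fit"))
  inp <- .state_inputs(state, dataset)
  xin <- .encoder_input(state$std, inp$X, inp$Sm)
  enc <- .encode_forward(state$params, xin, state$bn)
  structure(list(mu_z = enc$mu_z, sigma_z = enc$sigma_z,
                 mu_t = enc$mu_t, sigma_t = enc$sigma_t),
            class = "variational_posterior")
}

#' Decode latent points to ZINB parameters
#'
#' Runs the decoder networks at given latent points, returning the
#' per-cell-per-gene ZINB parameters: mean expression fractions `rho`
#' (rows sum to 1 via the softmax output), dropout probabilities `alpha`
#' (sigmoid link), and gene-wise inverse dispersions `theta`.
#'
#' @param state A `zinbmix_fit`.
#' @param z n x d matrix of latent points.
#' @param batch Batch labels for the n cells (known levels).
#' @return A `decoder_output` list with `rho`, `alpha`, `theta`.
#' @export
decode <- function(state, z, batch) {
  stopifnot(inherits(state, "zinbmix_fit"))
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  b <- factor(as.character(batch), levels = state$batch_levels)
  if (anyNA(b)) stop("unseen batch label")
  dec <- .decode_forward(state$params, z, one_hot(b), state$bn)
  structure(list(rho = dec$rho, alpha = sigmoid(dec$a),
                 theta = exp(state$params$log_theta)),
            class = "decoder_output")
}

#' Reparameterized latent draws
#'
#' Samples z = mu_z + sigma_z * eps (eps standard normal) and
#' t = exp(mu_t + sigma_t * eps'), i.e. a log-normal scaling factor, so
#' that draws are differentiable functions of the posterior parameters.
#'
#' @param posterior A `variational_posterior` from [encode()].
#' @param L Number of Monte Carlo samples (>= 1).
#' @param seed Optional seed; when given, draws are reproducible and the
#'   caller's RNG stream is left untouched.
#' @return A `latent_samples` list: `z` and `t` are lists of length L
#'   (n x d matrices and length-n positive vectors), `eps_z`/`eps_t` hold
#'   the underlying noise.
#' @export
sample_latent <- function(posterior, L = 1, seed = NULL) {
  stopifnot(inherits(posterior, "variational_posterior"), L >= 1)
  draw <- function() {
    n <- nrow(posterior$mu_z); d <- ncol(posterior$mu_z)
    eps_z <- lapply(seq_len(L), function(l) matrix(stats::rnorm(n * d), n, d))
    eps_t <- lapply(seq_len(L), function(l) stats::rnorm(n))
    list(eps_z = eps_z, eps_t = eps_t)
  }
  e <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  z <- lapply(e$eps_z, function(ez) posterior$mu_z + posterior$sigma_z * ez)
  t <- lapply(e$eps_t, function(et) exp(posterior$mu_t + posterior$sigma_t * et))
  structure(list(z = z, t = t, eps_z = e$eps_z, eps_t = e$eps_t),
            class = "latent_samples")
}

#' One stochastic gradient step on the variational bound
#'
#' Performs a single Adam ascent step on the minibatch estimator of the
#' bound for the network/dispersion parameter block. The Gaussian-mixture
#' block (weights and means) is frozen during this operation. Monte Carlo
#' noise is drawn from the current RNG stream.
#'
#' @param state A `zinbmix_fit`.
#' @param dataset A [count_dataset()].
#' @param cells Optional integer index selecting the minibatch (default:
#'   all cells).
#' @return List with the updated `state` and the minibatch estimator
#'   `value` (evaluated at the pre-update parameters).
#' @export
gradient_step <- function(state, dataset, cells = NULL) {
  stopifnot(inherits(state, "zinbmix_fit"))
  slice <- if (is.null(cells)) dataset else subset_cells(dataset, cells)
  inp <- .state_inputs(state, slice)
  xin <- if (!is.null(state$cache) && !is.null(cells)) {
    list(z = state$cache$z[cells, , drop = FALSE],
         t = state$cache$t[cells, , drop = FALSE])
  }
  n <- nrow(inp$X); d <- state$config$latent_dim; L <- state$config$mc_samples
  eps_z <- lapply(seq_len(L), function(l) matrix(stats::rnorm(n * d), n, d))
  eps_t <- lapply(seq_len(L), function(l) stats::rnorm(n))
  pdrop <- state$config$input_dropout
  drop_mask <- if (pdrop > 0) {
    matrix(stats::rbinom(n * state$n_genes, 1, 1 - pdrop) / (1 - pdrop),
           n, state$n_genes)
  }
  bp <- .elbo_backprop(state$params, state$std, inp$X, inp$Sm, inp$bidx,
                       state$prior, state$lib_prior, eps_z, eps_t,
                       drop_mask = drop_mask, xin = xin)
  if (!is.finite(bp$value)) {
    bad <- which(!is.finite(bp$per_cell))
    stop(sprintf("non-finite minibatch estimator (cell index %s)",
                 if (length(bad)) bad[1] else "unknown"))
  }
  if (!all(vapply(bp$grads, function(x) all(is.finite(x)), TRUE)))
    stop("non-finite gradient; aborting step")
  upd <- .adam_step(state$params, bp$grads, state$opt,
                    state$config$learning_rate)
  state$params <- upd$params
  state$opt <- upd$opt
  mo <- .BN_MOMENTUM
  for (nm in names(state$bn)) {
    state$bn[[nm]]$m <- mo * state$bn[[nm]]$m + (1 - mo) * bp$bn_batch[[nm]]$m
    state$bn[[nm]]$v <- mo * state$bn[[nm]]$v + (1 - mo) * bp$bn_batch[[nm]]$v
  }
  list(state = state, value = bp$value, z_draws = bp$z_draws)
}

#' One EM iteration for the Gaussian-mixture block
#'
#' Given latent draws accumulated over an epoch (network block frozen),
#' performs one E-step (closed-form responsibilities under the current
#' weights and means) and one M-step: each new mean is the
#' responsibility-weighted average of the draws and each new weight the
#' normalized responsibility mass.
#'
#' A component whose responsibility mass falls below `empty_tol` is
#' re-seeded at the draw farthest from all current means, with a small
#' weight folded back into the simplex; the event is recorded in the
#' `"reseeded"` attribute.
#'
#' @param z_samples M x d matrix of latent draws (all cells, all Monte
#'   Carlo samples).
#' @param prior Current [gmm_prior()].
#' @param empty_tol Relative mass below which a component counts as empty.
#' @return Updated `gmm_prior`.
#' @export
em_update <- function(z_samples, prior, empty_tol = 1e-10) {
  stopifnot(inherits(prior, "gmm_prior"))
  if (!is.matrix(z_samples)) z_samples <- matrix(z_samples, ncol = prior$d)
  M <- nrow(z_samples)
  q <- gmm_responsibilities(z_samples, prior)
  mass <- colSums(q)
  empty <- mass / M < empty_tol
  mu <- prior$mu
  ok <- !empty
  mu[ok, ] <- (t(q[, ok, drop = FALSE]) %*% z_samples) / mass[ok]
  pi_new <- mass / M
  reseeded <- integer(0)
  if (any(empty)) {
    for (c in which(empty)) {
      dist_to_means <- apply(z_samples, 1L, function(zz)
        min(sqrt(colSums((t(mu) - zz)^2))))
      far <- which.max(dist_to_means)
      mu[c, ] <- z_samples[far, ]
      pi_new[c] <- 1 / M
      reseeded <- c(reseeded, c)
    }
    pi_new <- pi_new / sum(pi_new)
  }
  pi_new <- pmax(pi_new, 1e-12)
  pi_new <- pi_new / sum(pi_new)
  out <- gmm_prior(pi_new, mu)
  attr(out, "reseeded") <- reseeded
  out
}

#' Fit the model by coordinate descent
#'
#' Trains the model on a count dataset: each epoch runs reparameterized
#' minibatch Adam steps on the variational bound with the mixture block
#' frozen, then (for C > 1) one EM update of the mixture weights and means
#' on the latent draws stored during that epoch, with responsibilities
#' recomputed under the current mixture parameters. The mixture is seeded
#' after a warm-up phase under a single standard-normal component by
#' k-means on the encoded cells. With `n_components = 1` the prior stays
#' the fixed standard normal and EM is skipped — the non-mixture ablation.
#'
#' Training stops at `max_epochs` or earlier when the smoothed epoch
#' estimator converges (relative change below `config$convergence_tol`
#' across a 10-epoch window). The fit is deterministic given
#' `config$seed`. If the estimator turns non-finite the fit aborts with a
#' warning and returns the last finite-epoch state.
#'
#' @param dataset A [count_dataset()].
#' @param n_components Number of mixture components C (>= 1).
#' @param config A [training_config()].
#' @param verbose Print per-epoch progress.
#' @return A `zinbmix_fit` with the full ELBO trace (one estimator value
#'   per epoch, summed over minibatches) in `$elbo_trace`.
#' @export
fit_zinbmix <- function(dataset, n_components,
                        config = training_config(), verbose = FALSE) {
  stopifnot(inherits(dataset, "count_dataset"), n_components >= 1)
  state <- .new_state(dataset, n_components, config)
  if (config$max_epochs == 0L) return(state)
  N <- nrow(dataset$counts)
  C <- as.integer(n_components)
  d <- config$latent_dim

  with_local_seed(config$seed, {
    state$params <- .smart_bias_init(
      .init_params(state$n_genes, length(state$batch_levels),
                   d, config$hidden_dim),
      dataset$counts, state$std, dataset$batch)
    state$bn <- .init_bn_stats(state$params, state$std, dataset$counts,
                               one_hot(dataset$batch))
    inp_full <- .state_inputs(state, dataset)
    state$cache <- .encoder_input(state$std, inp_full$X, inp_full$Sm)
    last_good <- state
    aborted <- FALSE

    for (e in seq_len(config$max_epochs)) {
      idx <- sample.int(N)
      starts <- seq(1L, N, by = config$minibatch_size)
      epoch_value <- 0
      draws <- vector("list", length(starts))
      ok <- TRUE
      for (k in seq_along(starts)) {
        cells <- idx[starts[k]:min(starts[k] + config$minibatch_size - 1L, N)]
        step <- tryCatch(gradient_step(state, dataset, cells),
                         error = function(err) err)
        if (inherits(step, "error")) {
          warning(sprintf("epoch %d aborted (%s); returning last-good state",
                          e, conditionMessage(step)))
          ok <- FALSE
          break
        }
        state <- step$state
        epoch_value <- epoch_value + step$value
        draws[[k]] <- do.call(rbind, step$z_draws)
      }
      if (!ok) { state <- last_good; aborted <- TRUE; break }

      # seed the mixture once the warm-up window is over
      if (C > 1L && !state$mixture_initialized &&
          e >= config$warmup_epochs) {
        mu_z <- encode(state, dataset)$mu_z
        km <- tryCatch(
          stats::kmeans(mu_z, centers = C, nstart = 5, iter.max = 50),
          error = function(err) NULL)
        if (is.null(km)) {
          centers <- mu_z[sample.int(N, C), , drop = FALSE]
          pi0 <- rep(1 / C, C)
        } else {
          centers <- km$centers
          pi0 <- pmax(tabulate(km$cluster, C) / N, 1e-3)
          pi0 <- pi0 / sum(pi0)
        }
        state$prior <- gmm_prior(pi0, centers)
        state$mixture_initialized <- TRUE
        state$em_events <- c(state$em_events,
                             sprintf("epoch %d: mixture seeded by k-means", e))
      } else if (C > 1L && state$mixture_initialized) {
        # EM draws re-sampled from the end-of-epoch encoder (evaluation
        # mode): draws stored during minibatches are perturbed by the
        # input-dropout regularizer and by within-epoch parameter drift,
        # which would displace the mixture relative to the encodings that
        # clustering actually uses
        post <- encode(state, dataset)
        Z <- do.call(rbind, lapply(seq_len(config$mc_samples), function(l)
          post$mu_z + post$sigma_z * matrix(stats::rnorm(N * d), N, d)))
        new_prior <- em_update(Z, state$prior)
        # EM restart guard: EM from the running prior can lag or lose the
        # cluster geometry while the encoder reorganizes; compare against
        # an EM step from a fresh k-means seeding of the same draws and
        # keep whichever maximizes the mixture likelihood on the draws
        km2 <- tryCatch(stats::kmeans(Z, centers = C, nstart = 2,
                                      iter.max = 30),
                        error = function(err) NULL)
        if (!is.null(km2)) {
          pi2 <- pmax(tabulate(km2$cluster, C) / nrow(Z), 1e-3)
          cand <- em_update(Z, gmm_prior(pi2 / sum(pi2), km2$centers))
          if (sum(gmm_log_density(Z, cand)) >
              sum(gmm_log_density(Z, new_prior))) {
            new_prior <- cand
            state$em_events <- c(state$em_events,
                                 sprintf("epoch %d: mixture re-seeded (restart guard)", e))
          }
        }
        rs <- attr(new_prior, "reseeded")
        if (length(rs))
          state$em_events <- c(state$em_events,
                               sprintf("epoch %d: component(s) %s re-seeded",
                                       e, paste(rs, collapse = ",")))
        attr(new_prior, "reseeded") <- NULL
        state$prior <- new_prior
      }

      state$elbo_trace <- c(state$elbo_trace, epoch_value)
      state$epochs_run <- e
      last_good <- state
      msg(sprintf("epoch %4d  estimator %.2f", e, epoch_value),
          verbose = verbose)

      # convergence on the smoothed epoch estimator
      burn <- if (C > 1L) config$warmup_epochs + 10L else 10L
      tr <- state$elbo_trace
      if (e >= burn && e >= 10L) {
        m_new <- mean(tr[(e - 4):e])
        m_old <- mean(tr[(e - 9):(e - 5)])
        if (abs(m_new - m_old) / (abs(m_old) + 1e-12) < config$convergence_tol) {
          state$converged <- TRUE
          msg(sprintf("converged at epoch %d", e), verbose = verbose)
          break
        }
      }
    }
    if (aborted) state <- last_good
  })
  state$cache <- NULL
  state
}
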