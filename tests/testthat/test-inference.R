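test_that("encoder outputs are deterministic, positive and finite", {
  ds <- tiny_dataset()
  st <- tiny_state(ds)
  # two identical cells in the same batch get identical posteriors
  X <- ds$counts
  dup <- count_dataset(rbind(X[1, ], X[1, ]) + 1, batch = c("a", "a"),
                       gene_names = ds$gene_names)
  post <- encode(st, dup)
  expect_equal(post$mu_z[1, ], post$mu_z[2, ])
  expect_equal(post$sigma_t[1], post$sigma_t[2])
  # scale outputs strictly positive, finite under extreme counts
  Xbig <- matrix(1e6, 3, ncol(X))
  big <- count_dataset(Xbig, batch = c("a", "b", "a"),
                       gene_names = ds$gene_names)
  pb <- encode(st, big)
  expect_true(all(pb$sigma_z > 0) && all(pb$sigma_t > 0))
  expect_true(all(is.finite(unlist(pb))))
  # unseen batch labels are rejected
  odd <- count_dataset(X[1:2, ], batch = c("zz", "zz"),
                       gene_names = ds$gene_names)
  expect_error(encode(st, odd), "unseen batch")
})

test_that("reparameterized draws honour the seed and the posterior", {
  ds <- tiny_dataset()
  st <- tiny_state(ds)
  post <- encode(st, ds)
  s1 <- sample_latent(post, L = 2, seed = 42)
  s2 <- sample_latent(post, L = 2, seed = 42)
  expect_identical(s1$z, s2$z)
  expect_identical(s1$t, s2$t)

  # sigma -> 0 limit gives z = mu exactly
  p0 <- post
  p0$sigma_z <- post$sigma_z * 0
  expect_equal(sample_latent(p0, seed = 1)$z[[1]], post$mu_z)

  # log t is Gaussian(mu_t, sigma_t^2): Monte Carlo check
  p1 <- structure(list(mu_z = matrix(0, 1e5, 1),
                       sigma_z = matrix(1, 1e5, 1),
                       mu_t = rep(1, 1e5), sigma_t = rep(0.5, 1e5)),
                  class = "variational_posterior")
  sm <- sample_latent(p1, seed = 3)
  lt <- log(sm$t[[1]])
  expect_lt(abs(mean(lt) - 1), 3 * 0.5 / sqrt(1e5))
  expect_true(all(sm$t[[1]] > 0))
})

test_that("backpropagated gradients match central finite differences", {
  withr::with_seed(42, {
    n <- 5; G <- 4; d <- 2; h <- 4
    X <- matrix(rpois(n * G, 3), n, G); X[1, 2] <- 0; X[3, 1] <- 0
    batch <- factor(c("a", "a", "b", "b", "b"))
    ds <- count_dataset(X, batch = batch)
    params <- zinbmix:::.init_params(G, 2, d, h)
    xl <- log1p(X); xn <- log1p(X / rowSums(X) * 1e4)
    std <- list(m = colMeans(xl), s = pmax(apply(xl, 2, sd), 1e-3),
                mn = colMeans(xn), sn = pmax(apply(xn, 2, sd), 1e-3),
                depth = 1e4)
    prior <- gmm_prior(c(0.4, 0.6), matrix(c(0, 0, 1, -1), 2, 2, byrow = TRUE))
    lp <- compute_library_prior(ds)
    Sm <- zinbmix:::one_hot(batch); bidx <- as.integer(batch)
    eps_z <- list(matrix(rnorm(n * d), n, d))
    eps_t <- list(rnorm(n))
    bp <- zinbmix:::.elbo_backprop(params, std, X, Sm, bidx, prior, lp,
                                   eps_z, eps_t)
    val <- function(p) zinbmix:::.elbo_backprop(p, std, X, Sm, bidx, prior,
                                                lp, eps_z, eps_t,
                                                want_grad = FALSE)$value
    worst <- 0
    for (nm in names(params)) {
      idx <- seq_len(min(6, length(params[[nm]])))
      for (i in idx) {
        hstep <- 1e-5 * max(1, abs(params[[nm]][i]))
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + hstep
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - hstep
        fd <- (val(pp) - val(pm)) / (2 * hstep)
        an <- bp$grads[[nm]][i]
        worst <- max(worst, abs(fd - an) / max(1e-2, abs(fd), abs(an)))
      }
    }
    expect_lt(worst, 1e-4)
  })
})

test_that("gradient_step freezes the mixture block and obeys lr = 0", {
  ds <- tiny_dataset()
  st <- tiny_state(ds, n_components = 2)
  st$prior <- gmm_prior(c(0.3, 0.7), matrix(rnorm(4), 2, 2))
  st$config$learning_rate <- 0
  withr::with_seed(9, out <- gradient_step(st, ds))
  expect_identical(out$state$params, st$params)  # lr 0: no movement
  expect_identical(out$state$prior, st$prior)    # mixture block frozen
  expect_true(is.finite(out$value))

  st$config$learning_rate <- 1e-3
  withr::with_seed(9, out2 <- gradient_step(st, ds))
  expect_false(identical(out2$state$params$ez_W1, st$params$ez_W1))
  expect_identical(out2$state$prior, st$prior)
})

test_that("one EM iteration reproduces closed-form special cases", {
  withr::with_seed(77, {
    # far-separated draws + matching means -> effectively one-hot
    # responsibilities: means become cluster averages, weights fractions
    z1 <- matrix(rnorm(60, 0, 0.1), 30, 2)
    z2 <- matrix(rnorm(40, 50, 0.1), 20, 2)
    Z <- rbind(z1, z2)
    pr <- gmm_prior(c(0.5, 0.5), rbind(c(0, 0), c(50, 50)))
    up <- em_update(Z, pr)
    expect_equal(up$mu[1, ], colMeans(z1), tolerance = 1e-6)
    expect_equal(up$mu[2, ], colMeans(z2), tolerance = 1e-6)
    expect_equal(up$pi, c(0.6, 0.4), tolerance = 1e-8)

    # identical means force uniform responsibilities: every new mean is
    # the global average and weights stay uniform
    pr2 <- gmm_prior(rep(1 / 3, 3), matrix(1.5, 3, 2))
    up2 <- em_update(Z, pr2)
    for (c in 1:3) expect_equal(up2$mu[c, ], colMeans(Z), tolerance = 1e-8)
    expect_equal(up2$pi, rep(1 / 3, 3), tolerance = 1e-8)
  })
})

test_that("EM recovers a known two-component mixture", {
  withr::with_seed(123, {
    N <- 2000; d <- 2
    truth_mu <- rbind(c(-3, 0), c(3, 0))   # separation 6
    truth_pi <- c(0.4, 0.6)
    comp <- sample(1:2, N, replace = TRUE, prob = truth_pi)
    Z <- truth_mu[comp, ] + matrix(rnorm(N * d), N, d)
    pr <- gmm_prior(c(0.5, 0.5), rbind(c(-1, 0.5), c(1, -0.5)))
    for (i in 1:20) pr <- em_update(Z, pr)
    o <- order(pr$mu[, 1])
    expect_lt(max(abs(pr$mu[o, ] - truth_mu)), 0.1)
    expect_lt(max(abs(pr$pi[o] - truth_pi)), 0.05)
  })
})

test_that("EM never decreases the mixture likelihood of fixed draws", {
  withr::with_seed(5, {
    Z <- rbind(matrix(rnorm(100, -2), 50, 2), matrix(rnorm(80, 2), 40, 2))
    pr <- gmm_prior(random_simplex(3), matrix(rnorm(6), 3, 2))
    ll <- sum(gmm_log_density(Z, pr))
    for (i in 1:15) {
      pr <- em_update(Z, pr)
      ll_new <- sum(gmm_log_density(Z, pr))
      expect_gte(ll_new, ll - 1e-8)
      ll <- ll_new
    }
  })
})

test_that("empty components are re-seeded at a remote draw", {
  Z <- matrix(rnorm(100), 50, 2)
  pr <- gmm_prior(c(0.5, 0.5), rbind(c(0, 0), c(1e4, 1e4)))
  up <- em_update(Z, pr)
  expect_true(2 %in% attr(up, "reseeded"))
  # re-seeded mean is one of the draws
  expect_true(any(apply(Z, 1, function(z) all(abs(z - up$mu[2, ]) < 1e-12))))
  expect_equal(sum(up$pi), 1)
})

test_that("fitting is seed-deterministic and honours max_epochs = 0", {
  ds <- tiny_dataset(n = 24, G = 10)
  cfg <- training_config(latent_dim = 2, hidden_dim = 8, max_epochs = 0,
                         seed = 4)
  st0 <- fit_zinbmix(ds, 2, cfg)
  expect_equal(st0$epochs_run, 0L)
  expect_length(st0$elbo_trace, 0)

  cfg$max_epochs <- 6L
  f1 <- fit_zinbmix(ds, 2, cfg)
  f2 <- fit_zinbmix(ds, 2, cfg)
  expect_identical(f1$elbo_trace, f2$elbo_trace)
  expect_identical(f1$params, f2$params)
  expect_length(f1$elbo_trace, 6)
})

test_that("C = 1 fits keep the fixed standard-normal prior", {
  ds <- tiny_dataset(n = 20, G = 10)
  cfg <- training_config(latent_dim = 2, hidden_dim = 8, max_epochs = 5,
                         seed = 2)
  f <- fit_zinbmix(ds, 1, cfg)
  expect_equal(f$prior$C, 1L)
  expect_equal(as.numeric(f$prior$mu), c(0, 0))
  q <- gmm_responsibilities(encode(f, ds)$mu_z, f$prior)
  expect_true(all(q == 1))   # responsibilities identically one
})
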