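test_that("library prior matches per-batch log-library statistics", {
  X <- rbind(rep(exp(2) / 3, 3), rep(exp(4) / 3, 3))
  X <- round(X)  # counts must be integers; use exact totals instead
  X <- matrix(c(4, 2, 1, 35, 10, 10), 2, 3, byrow = TRUE)
  # construct totals e^2 ~ 7.39 is not integral, so check the formula on
  # exact integer totals instead: totals 8 and 64 -> log 8, log 64
  X <- matrix(c(4, 2, 2, 32, 16, 16), 2, 3, byrow = TRUE)
  ds <- count_dataset(X)
  lp <- compute_library_prior(ds)
  expect_equal(unname(lp$mu_bar), mean(c(log(8), log(64))))
  expect_equal(unname(lp$sigma_bar_sq),
               mean((c(log(8), log(64)) - mean(c(log(8), log(64))))^2))

  # identical totals: population variance is 0, floored
  ds2 <- count_dataset(matrix(5L, 4, 3))
  expect_equal(unname(compute_library_prior(ds2)$sigma_bar_sq), 1e-4)

  # 6 cells, 2 batches, arbitrary counts vs an explicit loop
  withr::with_seed(7, {
    X <- matrix(rpois(6 * 5, 9) + 1, 6, 5)
    b <- c("u", "u", "v", "v", "v", "u")
    ds3 <- count_dataset(X, batch = b)
    lp3 <- compute_library_prior(ds3)
    for (lev in c("u", "v")) {
      ll <- log(rowSums(X)[b == lev])
      expect_equal(unname(lp3$mu_bar[lev]), mean(ll))
      expect_equal(unname(lp3$sigma_bar_sq[lev]),
                   sum((ll - mean(ll))^2) / length(ll))
    }
  })

  # zero-total cell is rejected with the cell named
  X0 <- matrix(c(0, 0, 0, 3, 1, 2), 2, 3, byrow = TRUE)
  ds0 <- structure(list(counts = X0, batch = factor(c("a", "a")),
                        gene_names = letters[1:3],
                        cell_names = c("bad_cell", "ok"),
                        true_labels = NULL), class = "count_dataset")
  expect_error(compute_library_prior(ds0), "bad_cell")
})

test_that("ZINB log-pmf agrees with closed forms and a quadrature oracle", {
  # alpha = 0 reduces to the plain negative binomial
  x <- c(0, 1, 4, 9)
  expect_equal(zinb_log_pmf(x, mu = 2.5, theta = 1.2, alpha = 0),
               dnbinom(x, size = 1.2, mu = 2.5, log = TRUE))

  # definition at zero
  expect_equal(zinb_log_pmf(0, mu = 3, theta = 2, alpha = 0.5),
               log(0.5 + 0.5 * dnbinom(0, size = 2, mu = 3)))

  # Gamma-Poisson quadrature oracle: NB(x; mu, theta) as the integral of
  # Poisson(x | t * w) over w ~ Gamma(rho, theta) with mu = t * rho
  quad_oracle <- function(x, mu, theta, alpha) {
    f <- function(w) dpois(x, w) * dgamma(w, shape = theta,
                                          rate = theta / mu)
    nb <- integrate(f, 0, Inf, rel.tol = 1e-12)$value
    log(alpha * (x == 0) + (1 - alpha) * nb)
  }
  expect_equal(zinb_log_pmf(3, 2.0, 1.5, 0.1), quad_oracle(3, 2.0, 1.5, 0.1),
               tolerance = 1e-8)
  expect_equal(zinb_log_pmf(0, 2.0, 1.5, 0.1), quad_oracle(0, 2.0, 1.5, 0.1),
               tolerance = 1e-8)
  expect_equal(zinb_log_pmf(7, 4.0, 0.7, 0.35), quad_oracle(7, 4.0, 0.7, 0.35),
               tolerance = 1e-8)

  # input validation and the alpha = 1 edge
  expect_error(zinb_log_pmf(-1, 1, 1, 0), "non-negative")
  expect_error(zinb_log_pmf(1.5, 1, 1, 0), "non-negative integers")
  expect_identical(zinb_log_pmf(2, 1, 1, 1), -Inf)
  expect_identical(zinb_log_pmf(0, 1, 1, 1), 0)
})

test_that("ZINB pmf normalizes over the support", {
  for (par in list(c(2, 1.5, 0.1), c(0.5, 4, 0.3), c(10, 2, 0.05))) {
    xmax <- 500
    p <- exp(zinb_log_pmf(0:xmax, par[1], par[2], par[3]))
    expect_lt(1 - sum(p), 1e-6)
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
})

test_that("GMM log-density matches naive summation", {
  expect_equal(gmm_log_density(c(0, 0), gmm_prior(1, matrix(0, 1, 2))),
               -log(2 * pi))
  # two symmetric components at +/- m evaluated at the origin
  m <- c(1.3, -0.4)
  pr <- gmm_prior(c(0.5, 0.5), rbind(m, -m))
  expect_equal(gmm_log_density(c(0, 0), pr),
               -sum(m^2) / 2 - log(2 * pi))
  # naive per-component summation oracle, C = 3
  withr::with_seed(3, {
    mu <- matrix(rnorm(6), 3, 2)
    pi <- random_simplex(3)
    z <- rnorm(2)
    naive <- log(sum(sapply(1:3, function(c)
      pi[c] * prod(dnorm(z, mu[c, ], 1)))))
    expect_equal(gmm_log_density(z, gmm_prior(pi, mu)), naive,
                 tolerance = 1e-12)
  })
  expect_error(gmm_log_density(c(0, 0, 0), gmm_prior(1, matrix(0, 1, 2))),
               "dimension")
})

test_that("responsibilities follow the closed-form quotient", {
  # equidistant z with equal weights -> uniform
  pr <- gmm_prior(rep(1 / 3, 3),
                  rbind(c(1, 0), c(-0.5, sqrt(3) / 2), c(-0.5, -sqrt(3) / 2)))
  expect_equal(as.numeric(gmm_responsibilities(c(0, 0), pr)), rep(1 / 3, 3))

  # far separation: z at a mean claims it
  pr2 <- gmm_prior(c(0.5, 0.5), rbind(c(0, 0), c(30, 0)))
  q <- gmm_responsibilities(c(30, 0), pr2)
  expect_gt(q[2], 1 - 1e-12)

  # direct quotient oracle, C = 3, d = 2
  withr::with_seed(11, {
    mu <- matrix(rnorm(6), 3, 2)
    pi <- random_simplex(3)
    z <- rnorm(2)
    dens <- sapply(1:3, function(c) pi[c] * prod(dnorm(z, mu[c, ], 1)))
    expect_equal(as.numeric(gmm_responsibilities(z, gmm_prior(pi, mu))),
                 dens / sum(dens), tolerance = 1e-12)
  })
})

test_that("responsibilities and density are Bayes-consistent", {
  withr::with_seed(19, {
    pr <- gmm_prior(random_simplex(4), matrix(rnorm(12), 4, 3))
    for (i in 1:20) {
      z <- rnorm(3, sd = 2)
      lq <- log(gmm_responsibilities(z, pr))
      lp <- gmm_log_density(z, pr)
      for (c in 1:4) {
        lhs <- lq[c] + lp
        rhs <- log(pr$pi[c]) + sum(dnorm(z, pr$mu[c, ], 1, log = TRUE))
        expect_equal(lhs, rhs, tolerance = 1e-9)
      }
    }
  })
})

test_that("library KL matches the Gaussian closed form and Monte Carlo", {
  ds <- tiny_dataset()
  lp <- compute_library_prior(ds)
  mb <- lp$mu_bar["a"]; vb <- lp$sigma_bar_sq["a"]
  # q identical to the prior
  expect_equal(unname(kl_library(mb, sqrt(vb), lp, "a")), 0)
  # mean shifted by one prior sd, same variance
  expect_equal(unname(kl_library(mb + sqrt(vb), sqrt(vb), lp, "a")), 0.5)
  # Monte-Carlo oracle
  withr::with_seed(23, {
    mu_q <- mb + 0.3; sd_q <- 0.5 * sqrt(vb) + 0.2
    x <- rnorm(1e6, mu_q, sd_q)
    mc <- mean(dnorm(x, mu_q, sd_q, log = TRUE) -
                 dnorm(x, mb, sqrt(vb), log = TRUE))
    se <- sd(dnorm(x, mu_q, sd_q, log = TRUE) -
               dnorm(x, mb, sqrt(vb), log = TRUE)) / 1000
    expect_lt(abs(unname(kl_library(mu_q, sd_q, lp, "a")) - mc), 3 * se)
  })
  expect_error(kl_library(1, 1, lp, "nope"), "unknown batch")
})

test_that("categorical KL matches direct summation", {
  p <- random_simplex(4)
  expect_equal(kl_categorical(p, p), 0)
  expect_equal(kl_categorical(c(0, 1, 0), rep(1 / 3, 3)), log(3))
  withr::with_seed(31, {
    q <- random_simplex(5); p5 <- random_simplex(5)
    expect_equal(kl_categorical(q, p5), sum(q * log(q / p5)))
  })
  expect_warning(v <- kl_categorical(c(0.5, 0.5), c(1, 0)), "Inf")
  expect_identical(v, Inf)
})

test_that("all KL terms are non-negative and vanish only at equality", {
  ds <- tiny_dataset()
  lp <- compute_library_prior(ds)
  withr::with_seed(41, {
    for (i in 1:25) {
      q <- random_simplex(4); p <- random_simplex(4)
      expect_gte(kl_categorical(q, p), 0)
      kl <- kl_library(rnorm(1, 2), rexp(1) + 0.05, lp, "b")
      expect_gte(unname(kl), -1e-12)
    }
  })
})

test_that("the bound estimator collapses correctly in degenerate settings", {
  ds <- tiny_dataset(n = 6, G = 5)
  st <- tiny_state(ds, n_components = 1, latent_dim = 2)
  post <- encode(st, ds)
  smp <- sample_latent(post, L = 1, seed = 99)
  dec <- decode(st, smp$z[[1]], ds$batch)
  pr1 <- gmm_prior(1, matrix(0, 1, 2))

  # C = 1: the estimator equals the scVI-style ELBO assembled term by term
  val <- elbo_estimate(ds, post, dec, pr1, st$lib_prior, smp)
  z <- smp$z[[1]]
  manual <- sum(
    -kl_library(post$mu_t, post$sigma_t, st$lib_prior, ds$batch) +
      sapply(seq_len(6), function(i) {
        mu_i <- smp$t[[1]][i] * dec$rho[i, ]
        sum(zinb_log_pmf(ds$counts[i, ], mu_i, dec$theta,
                         dec$alpha[i, ])) -
          sum(dnorm(z[i, ], post$mu_z[i, ], post$sigma_z[i, ], log = TRUE)) +
          sum(dnorm(z[i, ], 0, 1, log = TRUE))
      }))
  expect_equal(val, manual, tolerance = 1e-8)

  # identical components: mixture terms collapse to a single Gaussian
  prC <- gmm_prior(rep(1 / 3, 3), matrix(0.4, 3, 2))
  valC <- elbo_estimate(ds, post, dec, prC, st$lib_prior, smp)
  pr_single <- gmm_prior(1, matrix(0.4, 1, 2))
  val1 <- elbo_estimate(ds, post, dec, pr_single, st$lib_prior, smp)
  expect_equal(valC, val1, tolerance = 1e-8)
})

test_that("the bound lies below an importance-sampling marginal estimate", {
  # tiny instance: 2 cells, 3 genes, d = 1
  withr::with_seed(55, {
    X <- matrix(c(2, 0, 5, 1, 3, 0), 2, 3)
    ds <- count_dataset(X)
    st <- fit_zinbmix(ds, 1, training_config(latent_dim = 1, hidden_dim = 4,
                                             max_epochs = 5, seed = 3,
                                             minibatch_size = 2))
    post <- encode(st, ds)
    smp <- sample_latent(post, L = 1, seed = 7)
    dec <- decode(st, smp$z[[1]], ds$batch)
    pr <- st$prior
    lb <- elbo_estimate(ds, post, dec, pr, st$lib_prior, smp)

    # importance sampling from the prior p(z) p(t): log p(x_n) per cell
    M <- 1e5
    logp <- 0; se2 <- 0
    for (i in 1:2) {
      zs <- matrix(rnorm(M), M, 1)
      ts <- exp(rnorm(M, st$lib_prior$mu_bar[1],
                      sqrt(st$lib_prior$sigma_bar_sq[1])))
      de <- decode(st, zs, rep("batch1", M))
      ll <- rowSums(matrix(
        zinb_log_pmf(rep(X[i, ], each = M), de$rho * ts,
                     rep(de$theta, each = M), de$alpha), M, 3))
      mx <- max(ll)
      w <- exp(ll - mx)
      logp <- logp + mx + log(mean(w))
      se2 <- se2 + (sd(w) / (mean(w) * sqrt(M)))^2
    }
    expect_lt(lb, logp + 3 * sqrt(se2))
  })
})
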