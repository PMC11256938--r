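# Shared fixtures, all generated in code.

# Small count dataset with two batches and mild structure.
tiny_dataset <- function(n = 12, G = 8, two_batches = TRUE, seed = 101) {
  withr::with_seed(seed, {
    X <- matrix(rpois(n * G, lambda = rep(c(3, 8), each = n * G / 2)[seq_len(n * G)]),
                n, G)
    X[1, 2] <- 0
    batch <- if (two_batches) rep(c("a", "b"), length.out = n) else NULL
    count_dataset(X, batch = batch)
  })
}

# Initialized (untrained) model state for a dataset.
tiny_state <- function(dataset, n_components = 2, latent_dim = 2,
                       hidden_dim = 8, seed = 5) {
  fit_zinbmix(dataset, n_components,
              training_config(latent_dim = latent_dim,
                              hidden_dim = hidden_dim,
                              max_epochs = 0, seed = seed))
}

# Random point on the C-simplex.
random_simplex <- function(C) {
  x <- rexp(C)
  x / sum(x)
}

# Brute-force ARI via explicit enumeration of all pairs and the printed
# pair-count formula; independent of the package implementation.
ari_bruteforce <- function(u, v) {
  n <- length(u)
  a <- b <- c <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      su <- u[i] == u[j]; sv <- v[i] == v[j]
      if (su && sv) a <- a + 1
      else if (su && !sv) b <- b + 1
      else if (!su && sv) c <- c + 1
      else d <- d + 1
    }
  }
  tp <- n * (n - 1) / 2
  brack <- (a + b) * (a + c) + (c + d) * (b + d)
  if (tp^2 - brack == 0) return(1)
  (tp * (a + d) - brack) / (tp^2 - brack)
}

# Direct NMI from the printed I(U,V) and H(U) formulas.
nmi_direct <- function(u, v) {
  n <- length(u)
  ct <- table(u, v)
  iuv <- 0
  for (p in seq_len(nrow(ct))) {
    for (q in seq_len(ncol(ct))) {
      npq <- ct[p, q]
      if (npq > 0)
        iuv <- iuv + npq / n * log(n * npq / (sum(ct[p, ]) * sum(ct[, q])))
    }
  }
  hu <- -sum(rowSums(ct) / n * log(rowSums(ct) / n))
  hv <- -sum(colSums(ct) / n * log(colSums(ct) / n))
  if (hu == 0 && hv == 0) return(1)
  iuv / max(hu, hv)
}
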