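# Internal model machinery: the four MLPs (z-encoder, t-encoder, rho- and
# alpha-decoders), the minibatch ELBO estimator and its hand-written
# backpropagation, and the Adam optimizer. All networks have one hidden
# layer with softplus activation (smooth, so gradients can be checked
# against finite differences). Encoder inputs are log1p counts
# standardized gene-wise, with the one-hot batch label appended; decoders
# take the latent draw with the one-hot batch label appended (scVI-style
# conditioning).

.LS_CLAMP <- 6  # |log sigma| bound for encoder scale heads

.init_params <- function(G, B, d, h) {
  he <- function(fin, fout) matrix(stats::rnorm(fin * fout, 0, sqrt(2 / fin)), fin, fout)
  xa <- function(fin, fout) matrix(stats::rnorm(fin * fout, 0, sqrt(1 / fin)), fin, fout)
  ine <- G + B; ind <- d + B
  list(
    ez_W1 = he(ine, h), ez_b1 = numeric(h),
    ez_g = rep(1, h),   ez_be = numeric(h),
    ez_Wm = xa(h, d),   ez_bm = numeric(d),
    ez_Ws = xa(h, d),   ez_bs = numeric(d),
    et_W1 = he(ine, h), et_b1 = numeric(h),
    et_g = rep(1, h),   et_be = numeric(h),
    et_Wm = xa(h, 1),   et_bm = numeric(1),
    et_Ws = xa(h, 1),   et_bs = numeric(1),
    dr_W1 = he(ind, h), dr_b1 = numeric(h),
    dr_g = rep(1, h),   dr_be = numeric(h),
    dr_W2 = xa(h, G),   dr_b2 = numeric(G),
    da_W1 = he(ind, h), da_b1 = numeric(h),
    da_g = rep(1, h),   da_be = numeric(h),
    da_W2 = xa(h, G),   da_b2 = numeric(G),
    log_theta = numeric(G)  # theta_g = exp(.), initialized at 1
  )
}

# Fresh running batch-norm statistics for the four hidden layers.
.init_bn <- function(h) {
  one <- list(m = numeric(h), v = rep(1, h))
  list(ez = one, et = one, dr = one, da = one)
}

# Initialize running batch-norm statistics from the dataset so that the
# evaluation-mode forward pass is consistent with the data-dependent
# weight initialization from the very first epoch (fresh m = 0, v = 1
# stats would leave hidden activations unstandardized and distort the
# principal-component start).
.init_bn_stats <- function(params, std, X, Sm) {
  xin <- .encoder_input(std, X, Sm)
  stat <- function(m) list(m = colMeans(m), v = apply(m, 2L, stats::var))
  ez_lin <- addb(xin$z %*% params$ez_W1, params$ez_b1)
  et_lin <- addb(xin$t %*% params$et_W1, params$et_b1)
  bn <- list(ez = stat(ez_lin), et = stat(et_lin))
  enc <- .encode_forward(params, xin, bn[c("ez", "et")])
  din <- cbind(enc$mu_z, Sm)
  bn$dr <- stat(addb(din %*% params$dr_W1, params$dr_b1))
  bn$da <- stat(addb(din %*% params$da_W1, params$da_b1))
  bn
}

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

# Batch normalization of hidden pre-activations. In training mode (run =
# NULL) statistics come from the minibatch; in evaluation mode the stored
# running statistics are used, making the forward pass deterministic.
.bn_forward <- function(x, gamma, beta, run = NULL) {
  if (is.null(run)) {
    m <- colMeans(x)
    v <- colMeans(x^2) - m^2
  } else {
    m <- run$m; v <- run$v
  }
  n <- nrow(x)
  inv <- 1 / sqrt(v + .BN_EPS)
  xhat <- (x - rep(m, each = n)) * rep(inv, each = n)
  y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(y = y, xhat = xhat, inv = inv, m = m, v = v)
}

# Backward through training-mode batch norm (batch statistics).
.bn_backward <- function(gy, gamma, bn) {
  n <- nrow(gy)
  dxhat <- gy * rep(gamma, each = n)
  dgamma <- colSums(gy * bn$xhat)
  dbeta <- colSums(gy)
  cm1 <- colMeans(dxhat)
  cm2 <- colMeans(dxhat * bn$xhat)
  dx <- rep(bn$inv, each = n) *
    (dxhat - rep(cm1, each = n) - bn$xhat * rep(cm2, each = n))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.zero_like <- function(params) lapply(params, function(p) p * 0)

# Data-dependent initialization. Adam's per-parameter step is ~lr, so
# within a few hundred steps the optimizer can only refine, not discover,
# large-scale structure; every piece with a cheap data-driven starting
# point therefore gets one:
#   - t-encoder mean bias: empirical mean log library size; its mean head
#     is initialized (via the +/- hidden-unit trick below) to a linear
#     least-squares readout of the per-cell log library size.
#   - rho-decoder output bias: log empirical gene proportions.
#   - dropout logit bias: mildly negative (most entries are not dropouts).
#   - gene dispersions: method of moments on library-scaled counts.
#   - z-encoder: principal-component initialization. Hidden units come in
#     +/- pairs carrying +v_j and -v_j for the j-th principal axis of the
#     standardized input; after batch norm the pair is antisymmetric, so
#     softplus(u) - softplus(-u) = u makes the mean head output exactly
#     the (standardized) PC scores at initialization. Remaining hidden
#     units keep their random weights.
.smart_bias_init <- function(params, X, std, batch = NULL) {
  # start the posterior scales small: with sigma ~ 1 the latent draws are
  # noisier than the cluster separation itself, and the decoder's best
  # early move is to ignore z entirely (posterior collapse); the scale
  # heads can still grow where the data wants more posterior variance
  params$ez_bs <- rep(-2, length(params$ez_bs))
  params$et_bs <- rep(-2, length(params$et_bs))
  params$et_bm <- mean(log(rowSums(X)))
  gm <- colSums(X) / sum(X)
  params$dr_b2 <- log(pmax(gm, 1e-8))
  params$da_b2 <- rep(-2, length(params$da_b2))
  # method-of-moments start for the gene dispersions on library-scaled
  # counts: theta = m^2 / (v - m), clipped to a sane range
  sf <- rowSums(X) / mean(rowSums(X))
  Xs <- X / sf
  m <- colMeans(Xs)
  v <- apply(Xs, 2L, stats::var)
  th <- ifelse(v > m, m^2 / (v - m), 100)
  params$log_theta <- log(pmin(pmax(th, 1e-2), 1e3))

  G <- ncol(X)
  d <- ncol(params$ez_Wm)
  h <- nrow(params$ez_Wm)
  xn <- log1p(X / rowSums(X) * std$depth)
  xs <- sweep(sweep(xn, 2L, std$mn, "-"), 2L, std$sn, "/")
  # batch-aware start: principal components of the within-batch centered
  # expression, so the latent begins free of batch offsets (the decoder,
  # conditioned on the batch label, owns them instead). The per-batch
  # centering is wired into the hidden units through the one-hot batch
  # input columns, so it also holds at run time.
  batch <- if (is.null(batch)) factor(rep("b1", nrow(X))) else factor(batch)
  B <- nlevels(batch)
  bmeans <- matrix(0, B, ncol(xs))
  if (B > 1) {
    for (bi in seq_len(B)) {
      rows <- which(as.integer(batch) == bi)
      bmeans[bi, ] <- colMeans(xs[rows, , drop = FALSE])
      xs[rows, ] <- sweep(xs[rows, , drop = FALSE], 2L, bmeans[bi, ], "-")
    }
  }
  if (2 * d <= h && nrow(X) > d + 1) {
    pcs <- min(d, ncol(xs), nrow(xs) - 1L)
    pc <- stats::prcomp(xs, rank. = pcs, center = FALSE, scale. = FALSE)
    sv <- pc$sdev[seq_len(pcs)]
    for (j in seq_len(pcs)) {
      vj <- pc$rotation[, j]
      params$ez_W1[seq_len(G), 2 * j - 1] <- vj
      params$ez_W1[-seq_len(G), 2 * j - 1] <- -as.numeric(bmeans %*% vj)
      params$ez_W1[seq_len(G), 2 * j] <- -vj
      params$ez_W1[-seq_len(G), 2 * j] <- as.numeric(bmeans %*% vj)
      params$ez_b1[c(2 * j - 1, 2 * j)] <- 0
      params$ez_Wm[, j] <- 0
      # batch norm standardizes the hidden pair, so the head weight sets
      # the latent scale: use the component's singular value to keep the
      # eigenvalue ordering (whitening would make bulk-noise components
      # as loud as the structured ones)
      params$ez_Wm[2 * j - 1, j] <- sv[j]
      params$ez_Wm[2 * j, j] <- -sv[j]
    }
  }
  # rho-decoder: inverse PCA map through +/- hidden pairs, so that at
  # initialization encoder and decoder together form a principal-component
  # autoencoder of the depth-normalized log expression and reconstruction
  # gradients reinforce, rather than scramble, the latent structure.
  if (2 * d <= nrow(params$dr_W2) && nrow(X) > d + 1) {
    pcs <- min(d, ncol(xs), nrow(xs) - 1L)
    pc <- stats::prcomp(xs, rank. = pcs, center = FALSE, scale. = FALSE)
    for (j in seq_len(pcs)) {
      params$dr_W1[, 2 * j - 1] <- 0
      params$dr_W1[j, 2 * j - 1] <- 1
      params$dr_W1[, 2 * j] <- 0
      params$dr_W1[j, 2 * j] <- -1
      params$dr_b1[c(2 * j - 1, 2 * j)] <- 0
      cj <- pc$sdev[j] * pc$rotation[, j] * std$sn
      params$dr_W2[2 * j - 1, ] <- cj
      params$dr_W2[2 * j, ] <- -cj
    }
    # batch pathway of the decoder: hidden pairs fed by the one-hot batch
    # columns emit the empirical per-batch gene offsets (in log mean
    # proportion), so batch effects are explained by the conditioning
    # label from the start rather than leaking into the latent space
    if (B > 1 && 2 * pcs + 2 * B <= nrow(params$dr_W2)) {
      pbm <- X / rowSums(X)
      gm <- pmax(colSums(X) / sum(X), 1e-8)
      pb <- as.numeric(table(batch)) / nrow(X)
      offs <- matrix(0, B, G)
      for (bi in seq_len(B)) {
        rows <- which(as.integer(batch) == bi)
        offs[bi, ] <- log(pmax(colMeans(pbm[rows, , drop = FALSE]), 1e-8)) -
          log(gm)
      }
      for (bi in seq_len(B)) {
        u <- 2 * pcs + 2 * bi - 1
        sdb <- sqrt(pb[bi] * (1 - pb[bi]) + 1e-8)
        params$dr_W1[, u] <- 0
        params$dr_W1[d + bi, u] <- 1
        params$dr_W1[, u + 1] <- 0
        params$dr_W1[d + bi, u + 1] <- -1
        params$dr_b1[c(u, u + 1)] <- 0
        params$dr_W2[u, ] <- offs[bi, ] * sdb
        params$dr_W2[u + 1, ] <- -offs[bi, ] * sdb
      }
      params$dr_b2 <- params$dr_b2 + as.numeric(pb %*% offs)
    }
  }
  if (2 <= nrow(params$et_Wm)) {
    xl <- log1p(X)
    xs <- sweep(sweep(xl, 2L, std$m, "-"), 2L, std$s, "/")
    ll <- log(rowSums(X))
    w <- tryCatch({
      xtx <- crossprod(xs) + diag(1e-2 * nrow(xs), ncol(xs))
      drop(solve(xtx, crossprod(xs, ll - mean(ll))))
    }, error = function(e) NULL)
    if (!is.null(w)) {
      fit_sd <- stats::sd(drop(xs %*% w))
      if (fit_sd > 1e-8) {
        params$et_W1[seq_len(G), 1] <- w
        params$et_W1[-seq_len(G), 1] <- 0
        params$et_W1[seq_len(G), 2] <- -w
        params$et_W1[-seq_len(G), 2] <- 0
        params$et_b1[1:2] <- 0
        params$et_Wm[, 1] <- 0
        params$et_Wm[1, 1] <- fit_sd   # undo batch-norm rescaling
        params$et_Wm[2, 1] <- -fit_sd
      }
    }
  }
  params
}

addb <- function(m, b) m + rep(b, each = nrow(m))

# Standardized encoder inputs for a slice of cells. The z-encoder sees
# depth-normalized log expression (library size is a technical nuisance
# owned by the scaling factor, so it is removed from the biological
# encoder's view); the t-encoder sees raw log1p counts, from which depth
# is inferred. Both are gene-wise standardized with dataset-level
# statistics and carry the one-hot batch label.
.encoder_input <- function(params_std, X, Sm) {
  n <- nrow(X)
  xn <- log1p(X / rowSums(X) * params_std$depth)
  xl <- log1p(X)
  zin <- (xn - rep(params_std$mn, each = n)) * rep(1 / params_std$sn, each = n)
  tin <- (xl - rep(params_std$m, each = n)) * rep(1 / params_std$s, each = n)
  list(z = cbind(zin, Sm), t = cbind(tin, Sm))
}

# Forward pass of the two encoder networks. `bn` = running statistics for
# evaluation mode; NULL uses minibatch statistics (training mode).
.encode_forward <- function(params, xin, bn = NULL) {
  z_lin <- addb(xin$z %*% params$ez_W1, params$ez_b1)
  z_bn <- .bn_forward(z_lin, params$ez_g, params$ez_be, bn$ez)
  Hz <- softplus(z_bn$y)
  mu_z <- addb(Hz %*% params$ez_Wm, params$ez_bm)
  ls_z_raw <- addb(Hz %*% params$ez_Ws, params$ez_bs)
  ls_z <- pmin(pmax(ls_z_raw, -.LS_CLAMP), .LS_CLAMP)

  t_lin <- addb(xin$t %*% params$et_W1, params$et_b1)
  t_bn <- .bn_forward(t_lin, params$et_g, params$et_be, bn$et)
  Ht <- softplus(t_bn$y)
  mu_t <- as.numeric(Ht %*% params$et_Wm) + params$et_bm
  ls_t_raw <- as.numeric(Ht %*% params$et_Ws) + params$et_bs
  ls_t <- pmin(pmax(ls_t_raw, -.LS_CLAMP), .LS_CLAMP)

  list(z_bn = z_bn, Hz = Hz, mu_z = mu_z, ls_z_raw = ls_z_raw,
       ls_z = ls_z, sigma_z = exp(ls_z),
       t_bn = t_bn, Ht = Ht, mu_t = mu_t, ls_t_raw = ls_t_raw,
       ls_t = ls_t, sigma_t = exp(ls_t))
}

# Forward pass of the two decoder networks at latent points z.
.decode_forward <- function(params, z, Sm, bn = NULL) {
  din <- cbind(z, Sm)
  r_lin <- addb(din %*% params$dr_W1, params$dr_b1)
  r_bn <- .bn_forward(r_lin, params$dr_g, params$dr_be, bn$dr)
  Hr <- softplus(r_bn$y)
  r <- addb(Hr %*% params$dr_W2, params$dr_b2)
  rho <- row_softmax(r)
  a_lin <- addb(din %*% params$da_W1, params$da_b1)
  a_bn <- .bn_forward(a_lin, params$da_g, params$da_be, bn$da)
  Ha <- softplus(a_bn$y)
  a <- addb(Ha %*% params$da_W2, params$da_b2)
  list(din = din, r_bn = r_bn, Hr = Hr, rho = rho,
       a_bn = a_bn, Ha = Ha, a = a)
}

# ZINB log-likelihood matrix and (optionally) its partial derivatives.
# X counts, MU means, A dropout logits (n x G); theta a length-G vector.
# The x = 0 branch is evaluated only on the zero entries (index subset),
# which keeps the dominant cost at a few transcendental passes over the
# dense positive part.
.zinb_ll_terms <- function(X, MU, theta, A, want_grad = FALSE) {
  n <- nrow(X); G <- ncol(X)
  TH <- matrix(theta, n, G, byrow = TRUE)
  log_th_row <- rep(log(theta), each = n)     # filled column-major like TH
  denom <- TH + MU
  ldenom <- log(denom)
  V <- TH * (log_th_row - ldenom)
  LG <- lgamma(X + TH) - rep(lgamma(theta), each = n) - lgamma(X + 1)
  nb <- LG + V + X * (log(MU) - ldenom)
  spa <- softplus(A)
  i0 <- which(X == 0)
  ll <- nb - spa
  A0 <- A[i0]; V0 <- V[i0]
  ll[i0] <- logaddexp(A0, V0) - spa[i0]
  out <- list(ll = ll)
  if (want_grad) {
    sa <- sigmoid(A)
    dv_dth <- (log_th_row - ldenom) + 1 - TH / denom
    dA <- -sa
    dMU <- X / MU - (X + TH) / denom
    dTH <- digamma(X + TH) - rep(digamma(theta), each = n) + dv_dth -
      X / denom
    pa <- sigmoid(A0 - V0)                    # dropout-branch weight at x=0
    dA[i0] <- pa - sa[i0]
    dMU[i0] <- (1 - pa) * (-TH[i0] / denom[i0])
    dTH[i0] <- (1 - pa) * dv_dth[i0]
    out$dA <- dA; out$dMU <- dMU; out$dTH <- dTH
  }
  out
}

# Minibatch ELBO estimator (the Algorithm-1 style Monte Carlo estimator of
# the mixture-unfolded bound) and, optionally, gradients with respect to
# every network parameter and log_theta. Noise `eps_z`/`eps_t` is passed in
# explicitly so the same draw can be replayed (finite-difference checks,
# seed determinism).
#
# X: n x G counts; Sm: n x B one-hot batch; bidx: batch index per cell.
.elbo_backprop <- function(params, std, X, Sm, bidx, prior, lib_prior,
                           eps_z, eps_t, want_grad = TRUE,
                           drop_mask = NULL, xin = NULL) {
  n <- nrow(X); G <- ncol(X); d <- ncol(prior$mu); L <- length(eps_z)
  theta <- exp(params$log_theta)

  if (is.null(xin)) xin <- .encoder_input(std, X, Sm)
  if (!is.null(drop_mask)) {
    # input dropout (training regularizer); gene features only, the
    # one-hot batch columns are never dropped
    xin$z[, seq_len(G)] <- xin$z[, seq_len(G)] * drop_mask
    xin$t[, seq_len(G)] <- xin$t[, seq_len(G)] * drop_mask
  }
  enc <- .encode_forward(params, xin)
  mb <- lib_prior$mu_bar[bidx]; vb <- lib_prior$sigma_bar_sq[bidx]
  kl_t <- 0.5 * log(vb) - enc$ls_t +
    (enc$sigma_t^2 + (enc$mu_t - mb)^2) / (2 * vb) - 0.5

  g <- if (want_grad) .zero_like(params) else NULL
  gmu_z <- matrix(0, n, d); gls_z <- matrix(0, n, d)
  gmu_t <- numeric(n); gls_t <- numeric(n)
  val_samples <- numeric(n)
  z_draws <- vector("list", L)
  logpi <- log(prior$pi)

  for (l in seq_len(L)) {
    eps <- eps_z[[l]]; epst <- eps_t[[l]]
    z <- enc$mu_z + enc$sigma_z * eps
    z_draws[[l]] <- z
    tfac <- exp(enc$mu_t + enc$sigma_t * epst)
    dec <- .decode_forward(params, z, Sm)
    MU <- dec$rho * tfac
    zb <- .zinb_ll_terms(X, MU, theta, dec$a, want_grad = want_grad)
    llcell <- rowSums(zb$ll)

    # -log q(z | x, s) at the reparameterized draw
    ent <- rowSums(0.5 * log(2 * pi) + enc$ls_z + 0.5 * eps^2)

    # mixture terms, computed literally as -KL(q(c|z)||p(c)) + E_q log p(z|c);
    # analytically this equals log p(z) under the closed-form q(c|z)
    lw <- .gmm_logweights(z, prior)
    lpz <- row_logsumexp(lw)
    q <- exp(lw - lpz)
    lognc <- sweep(lw, 2L, logpi, "-")           # log N(z; mu_c, I)
    qs <- pmax(q, 1e-300)
    mixval <- -rowSums(q * (log(qs) - rep(logpi, each = n))) +
      rowSums(q * lognc)

    val_samples <- val_samples + llcell + ent + mixval

    if (want_grad) {
      # --- observation-model gradients
      g$log_theta <- g$log_theta + colSums(zb$dTH) * theta
      g_t <- rowSums(zb$dMU * dec$rho)
      P <- zb$dMU * tfac
      g_r <- dec$rho * (P - rowSums(P * dec$rho))

      # --- rho decoder
      g$dr_W2 <- g$dr_W2 + crossprod(dec$Hr, g_r)
      g$dr_b2 <- g$dr_b2 + colSums(g_r)
      gy <- tcrossprod(g_r, params$dr_W2) * sigmoid(dec$r_bn$y)
      bnb <- .bn_backward(gy, params$dr_g, dec$r_bn)
      g$dr_g <- g$dr_g + bnb$dgamma
      g$dr_be <- g$dr_be + bnb$dbeta
      g$dr_W1 <- g$dr_W1 + crossprod(dec$din, bnb$dx)
      g$dr_b1 <- g$dr_b1 + colSums(bnb$dx)
      g_z <- tcrossprod(bnb$dx, params$dr_W1)[, seq_len(d), drop = FALSE]

      # --- alpha decoder
      g$da_W2 <- g$da_W2 + crossprod(dec$Ha, zb$dA)
      g$da_b2 <- g$da_b2 + colSums(zb$dA)
      gy <- tcrossprod(zb$dA, params$da_W2) * sigmoid(dec$a_bn$y)
      bnb <- .bn_backward(gy, params$da_g, dec$a_bn)
      g$da_g <- g$da_g + bnb$dgamma
      g$da_be <- g$da_be + bnb$dbeta
      g$da_W1 <- g$da_W1 + crossprod(dec$din, bnb$dx)
      g$da_b1 <- g$da_b1 + colSums(bnb$dx)
      g_z <- g_z + tcrossprod(bnb$dx, params$da_W1)[, seq_len(d), drop = FALSE]

      # --- mixture gradient: d log p(z) / dz = sum_c q_c (mu_c - z)
      g_z <- g_z + q %*% prior$mu - z

      gmu_z <- gmu_z + g_z
      gls_z <- gls_z + g_z * enc$sigma_z * eps + 1   # +1 from -log q entropy
      gmu_t <- gmu_t + g_t * tfac
      gls_t <- gls_t + g_t * tfac * enc$sigma_t * epst
    }
  }

  value <- sum(-kl_t + val_samples / L)

  if (want_grad) {
    g <- lapply(g, function(x) x / L)   # decoder/theta parts are sample means
    gmu_z <- gmu_z / L
    gls_z <- (gls_z / L) * (abs(enc$ls_z_raw) < .LS_CLAMP)
    gmu_t <- gmu_t / L - (enc$mu_t - mb) / vb
    gls_t <- (gls_t / L + 1 - enc$sigma_t^2 / vb) *
      (abs(enc$ls_t_raw) < .LS_CLAMP)

    # --- z-encoder
    g$ez_Wm <- g$ez_Wm + crossprod(enc$Hz, gmu_z)
    g$ez_bm <- g$ez_bm + colSums(gmu_z)
    g$ez_Ws <- g$ez_Ws + crossprod(enc$Hz, gls_z)
    g$ez_bs <- g$ez_bs + colSums(gls_z)
    gy <- (tcrossprod(gmu_z, params$ez_Wm) + tcrossprod(gls_z, params$ez_Ws)) *
      sigmoid(enc$z_bn$y)
    bnb <- .bn_backward(gy, params$ez_g, enc$z_bn)
    g$ez_g <- g$ez_g + bnb$dgamma
    g$ez_be <- g$ez_be + bnb$dbeta
    g$ez_W1 <- g$ez_W1 + crossprod(xin$z, bnb$dx)
    g$ez_b1 <- g$ez_b1 + colSums(bnb$dx)

    # --- t-encoder
    g$et_Wm <- g$et_Wm + crossprod(enc$Ht, matrix(gmu_t, ncol = 1))
    g$et_bm <- g$et_bm + sum(gmu_t)
    g$et_Ws <- g$et_Ws + crossprod(enc$Ht, matrix(gls_t, ncol = 1))
    g$et_bs <- g$et_bs + sum(gls_t)
    gy <- (tcrossprod(matrix(gmu_t, ncol = 1), params$et_Wm) +
             tcrossprod(matrix(gls_t, ncol = 1), params$et_Ws)) *
      sigmoid(enc$t_bn$y)
    bnb <- .bn_backward(gy, params$et_g, enc$t_bn)
    g$et_g <- g$et_g + bnb$dgamma
    g$et_be <- g$et_be + bnb$dbeta
    g$et_W1 <- g$et_W1 + crossprod(xin$t, bnb$dx)
    g$et_b1 <- g$et_b1 + colSums(bnb$dx)
  }

  bn_batch <- list(ez = list(m = enc$z_bn$m, v = enc$z_bn$v),
                   et = list(m = enc$t_bn$m, v = enc$t_bn$v),
                   dr = list(m = dec$r_bn$m, v = dec$r_bn$v),
                   da = list(m = dec$a_bn$m, v = dec$a_bn$v))
  list(value = value, grads = g, enc = enc, z_draws = z_draws,
       per_cell = -kl_t + val_samples / L, bn_batch = bn_batch)
}

# One Adam ascent step; returns updated params and optimizer state. When
# the second moment was pre-initialized from probe gradients (moment
# warm-up), its bias correction is skipped: with v estimated at t = 0,
# dividing by 1 - beta2^t would massively inflate early steps for
# parameters whose true gradients are tiny, wiping out data-dependent
# initialization within the first few dozen steps.
.adam_step <- function(params, grads, opt, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(opt)) {
    opt <- list(m = .zero_like(params), v = .zero_like(params), t = 0L,
                v_warm = FALSE)
  }
  opt$t <- opt$t + 1L
  b1t <- 1 - beta1^opt$t
  b2t <- if (isTRUE(opt$v_warm)) 1 else 1 - beta2^opt$t
  for (nm in names(params)) {
    gn <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gn
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gn^2
    params[[nm]] <- params[[nm]] +
      lr * (opt$m[[nm]] / b1t) / (sqrt(opt$v[[nm]] / b2t) + eps)
  }
  list(params = params, opt = opt)
}

# Pre-initialize Adam's second moment with squared gradients measured on
# probe minibatches at the initial parameters (no updates applied).
.adam_warm_start <- function(params, probe_grads) {
  v <- .zero_like(params)
  for (g in probe_grads) {
    for (nm in names(v)) v[[nm]] <- v[[nm]] + g[[nm]]^2
  }
  for (nm in names(v)) v[[nm]] <- v[[nm]] / length(probe_grads)
  list(m = .zero_like(params), v = v, t = 0L, v_warm = TRUE)
}
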