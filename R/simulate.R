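# Splat-style synthetic scRNA-seq counts: grouped cells with lognormal
# differential-expression factors, per-cell lognormal library sizes,
# Gamma-Poisson (negative binomial) counts with a mean-dependent BCV, an
# experiment-wide logistic dropout layer, and optional multiplicative
# batch factors.

# Calibration constant: shift applied to dropout_mid so that the sweep
# -1.5 -> 0.5 lands the realized dropout fraction (positive counts zeroed)
# at roughly 5% -> 25% at the default 2500 x 2500 scenario scale.
.DROPOUT_MID_OFFSET <- 1.0

#' Define a simulation scenario
#'
#' Full parameterization of one synthetic experiment. Group sizes follow
#' a geometric sequence with ratio `group_ratio` (1 = balanced); batch
#' sizes follow a geometric sequence with ratio `batch_ratio`.
#'
#' @param n_cells,n_genes Matrix dimensions (defaults 2500 x 2500).
#' @param n_groups Number of cell groups.
#' @param group_ratio Geometric ratio r in (0, 1] of successive group
#'   sizes; 1 gives balanced groups.
#' @param de_fac_scale Log-scale sd of the lognormal differential
#'   expression factors (default 0.2).
#' @param de_prob Fraction of genes receiving a DE factor per group.
#' @param de_fac_loc Log-scale location of the DE factors.
#' @param dropout_mid Midpoint of the logistic dropout curve; larger
#'   values produce more dropout. The studied sweep is [-1.5, 0.5].
#' @param dropout_shape Slope of the logistic dropout curve (default -1).
#' @param n_batches Number of batches (1 = no batch effects).
#' @param batch_ratio Geometric ratio of successive batch sizes.
#' @param batch_fac_loc,batch_fac_scale Lognormal parameters of the
#'   per-batch gene-wise multiplicative factors.
#' @param bcv Common biological coefficient of variation floor.
#' @param lib_meanlog,lib_sdlog Lognormal library-size parameters
#'   (defaults give median total ~60000, the splat convention).
#' @param mean_sdlog Log-scale sd of gene base expression levels.
#' @param seed Seed; identical scenarios give bitwise-identical counts.
#' @return A `sim_scenario` list.
#' @export
simulation_scenario <- function(n_cells = 2500, n_genes = 2500,
                                n_groups = 3, group_ratio = 1.0,
                                de_fac_scale = 0.2, de_prob = 0.1,
                                de_fac_loc = 0.1,
                                dropout_mid = -1.5, dropout_shape = -1,
                                n_batches = 1, batch_ratio = 0.7,
                                batch_fac_loc = 0.1, batch_fac_scale = 0.1,
                                bcv = 0.1,
                                lib_meanlog = 11, lib_sdlog = 0.2,
                                mean_sdlog = 1.0, seed = 1) {
  stopifnot(n_groups >= 1, group_ratio > 0, group_ratio <= 1,
            n_batches >= 1, batch_ratio > 0, batch_ratio <= 1)
  if (n_groups > n_cells) stop("more groups than cells")
  structure(as.list(environment()), class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(paste0("sim_scenario: %d cells x %d genes, %d group(s) ",
                     "(r = %.2f), %d batch(es), dropout_mid = %.2f, ",
                     "seed = %d\n"),
              x$n_cells, x$n_genes, x$n_groups, x$group_ratio, x$n_batches,
              x$dropout_mid, x$seed))
  invisible(x)
}

# Sizes following a geometric sequence with the given ratio, summing to n,
# each at least 1 (largest-remainder rounding).
.geometric_sizes <- function(n, k, ratio) {
  w <- ratio^(seq_len(k) - 1)
  exact <- n * w / sum(w)
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  if (any(sizes == 0)) {
    for (i in which(sizes == 0)) {
      big <- which.max(sizes)
      sizes[i] <- 1; sizes[big] <- sizes[big] - 1
    }
  }
  sizes
}

# Lognormal effect factors in splat style: a fraction sel_prob of genes is
# selected; factors are drawn lognormal, forced >= 1, and inverted (down-
# regulated) with probability neg_prob; unselected genes get factor 1.
.lnorm_factors <- function(n_genes, sel_prob, neg_prob, loc, scale) {
  sel <- stats::runif(n_genes) < sel_prob
  facs <- rep(1, n_genes)
  ns <- sum(sel)
  if (ns > 0) {
    f <- stats::rlnorm(ns, loc, scale)
    dir <- ifelse(stats::runif(ns) < neg_prob, -1, 1)
    dir[f < 1] <- -dir[f < 1]
    facs[sel] <- pmax(f, 1 / f)^dir
  }
  facs
}

#' Simulate a grouped, zero-inflated scRNA-seq count dataset
#'
#' Generative pathway: lognormal gene base means; per-group DE factors on
#' a random gene subset; per-batch multiplicative factors on all genes
#' (when `n_batches > 1`); per-cell expected expression normalized to
#' proportions and scaled by a lognormal library size; Gamma-Poisson
#' (negative binomial) sampling with BCV
#' `(bcv + 1/sqrt(lambda))^2`; finally entries are zeroed with
#' probability `plogis(dropout_shape * (log(lambda) - mid'))` where
#' `mid'` is `dropout_mid` plus a fixed calibration offset, oriented so a
#' larger `dropout_mid` produces more dropout.
#'
#' @param scenario A [simulation_scenario()].
#' @return A [count_dataset()] with `true_labels` (groups) and `batch`
#'   recorded. All-zero genes are dropped by the constructor.
#' @export
simulate_counts <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  with_local_seed(sc$seed, {
    gs <- .geometric_sizes(sc$n_cells, sc$n_groups, sc$group_ratio)
    group <- rep(seq_len(sc$n_groups), gs)
    bs <- .geometric_sizes(sc$n_cells, sc$n_batches, sc$batch_ratio)
    batch <- sample(rep(seq_len(sc$n_batches), bs))  # batches cut across groups

    base <- stats::rlnorm(sc$n_genes, meanlog = 0, sdlog = sc$mean_sdlog)
    de <- vapply(seq_len(sc$n_groups), function(g)
      .lnorm_factors(sc$n_genes, sc$de_prob, 0.5, sc$de_fac_loc,
                     sc$de_fac_scale),
      numeric(sc$n_genes))                          # genes x groups
    bf <- vapply(seq_len(sc$n_batches), function(b)
      if (sc$n_batches > 1)
        .lnorm_factors(sc$n_genes, 1, 0.5, sc$batch_fac_loc,
                       sc$batch_fac_scale)
      else rep(1, sc$n_genes),
      numeric(sc$n_genes))                          # genes x batches

    means <- t(de[, group, drop = FALSE] * bf[, batch, drop = FALSE]) *
      rep(base, each = sc$n_cells)                  # cells x genes
    props <- means / rowSums(means)
    lib <- stats::rlnorm(sc$n_cells, sc$lib_meanlog, sc$lib_sdlog)
    lambda <- props * lib

    phi <- (sc$bcv + 1 / sqrt(lambda))^2
    w <- stats::rgamma(length(lambda), shape = 1 / phi, scale = lambda * phi)
    y <- stats::rpois(length(lambda), w)

    pdrop <- stats::plogis(sc$dropout_shape *
                             (log(lambda) -
                                (sc$dropout_mid + .DROPOUT_MID_OFFSET)))
    keep <- stats::runif(length(lambda)) >= pdrop
    x <- matrix(y * keep, sc$n_cells, sc$n_genes)

    count_dataset(x,
                  batch = sprintf("batch%d", batch),
                  true_labels = sprintf("group%d", group),
                  gene_names = sprintf("gene%d", seq_len(sc$n_genes)),
                  cell_names = sprintf("cell%d", seq_len(sc$n_cells)))
  })
}

#' Scenario grids for the simulation study
#'
#' The four studied designs: `"balanced"` sweeps 3-7 equally sized groups
#' against dropout midpoints {-1.5, -1, -0.5, 0, 0.5}; `"imbalanced"`
#' fixes 5 groups and sweeps the group-size ratio {0.6, ..., 1.0} against
#' the same dropout midpoints; the `"batch_*"` variants add 3 batches
#' with size ratio 0.7. Each grid cell is replicated with `n_seeds`
#' random seeds.
#'
#' @param kind One of `"balanced"`, `"imbalanced"`, `"batch_balanced"`,
#'   `"batch_imbalanced"`.
#' @param n_seeds Replicate seeds per grid cell (default 10).
#' @param n_cells,n_genes Dataset dimensions applied to every scenario.
#' @return List of [simulation_scenario()] objects.
#' @export
scenario_grid <- function(kind = c("balanced", "imbalanced",
                                   "batch_balanced", "batch_imbalanced"),
                          n_seeds = 10, n_cells = 2500, n_genes = 2500) {
  kind <- match.arg(kind)
  mids <- c(-1.5, -1, -0.5, 0, 0.5)
  cells <- if (kind %in% c("balanced", "batch_balanced")) {
    expand.grid(n_groups = 3:7, group_ratio = 1.0, dropout_mid = mids)
  } else {
    expand.grid(n_groups = 5, group_ratio = seq(0.6, 1.0, by = 0.1),
                dropout_mid = mids)
  }
  nb <- if (startsWith(kind, "batch_")) 3L else 1L
  out <- list()
  for (i in seq_len(nrow(cells))) {
    for (s in seq_len(n_seeds)) {
      out[[length(out) + 1L]] <- simulation_scenario(
        n_cells = n_cells, n_genes = n_genes,
        n_groups = cells$n_groups[i], group_ratio = cells$group_ratio[i],
        dropout_mid = cells$dropout_mid[i],
        n_batches = nb, batch_ratio = 0.7,
        seed = s)
    }
  }
  out
}
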