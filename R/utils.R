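# Internal numerical helpers shared across the package.

softplus <- function(x) {
  # log(1 + exp(x)), stable for large |x|
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Row-wise softmax of a matrix.
row_softmax <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

# Element-wise log(exp(a) + exp(b)) for two matrices/vectors of equal shape.
logaddexp <- function(a, b) {
  mx <- pmax(a, b)
  mx + log1p(exp(-abs(a - b)))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# One-hot matrix for a factor, columns in level order.
one_hot <- function(f) {
  f <- as.factor(f)
  m <- matrix(0, length(f), nlevels(f))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}
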