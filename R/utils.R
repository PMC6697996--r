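# Internal numeric helpers shared across layers.

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector.
#' @return log(sum(exp(x))) computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix.
logsumexp_rows <- function(M) {
  m <- apply(M, 1L, max)
  m + log(rowSums(exp(M - m)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Evaluate an expression without disturbing the global RNG stream
#' @keywords internal
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 32-bit-safe seed derived from a parameter name and a base
# seed, so initialization of a tensor does not depend on the order in which
# tensors are created (two models sharing a tensor name initialize it
# identically under the same base seed).
name_seed <- function(name, seed) {
  codes <- utf8ToInt(name)
  h <- 0
  for (k in seq_along(codes)) h <- (h * 31 + codes[k]) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

init_param <- function(name, dims, seed, dist = c("uniform", "zero"),
                       range = 0.1) {
  dist <- match.arg(dist)
  n <- prod(dims)
  vals <- if (dist == "zero") rep(0, n) else
    with_local_seed(name_seed(name, seed), stats::runif(n, -range, range))
  if (length(dims) == 1L) vals else array(vals, dim = dims)
}

# Inverted dropout: mask entries are 0 or 1/(1-rate) so evaluation needs no
# rescaling.  Returns NULL when inactive.
dropout_mask <- function(dims, rate, train) {
  if (!train || rate <= 0) return(NULL)
  keep <- stats::runif(prod(dims)) >= rate
  array(as.numeric(keep) / (1 - rate), dim = dims)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

# Global L2-norm gradient clipping: rescale the whole gradient list so its
# joint norm does not exceed max_norm.
clip_gradients <- function(grads, max_norm) {
  ss <- sum(vapply(grads, function(g) sum(g * g), numeric(1)))
  nrm <- sqrt(ss)
  if (is.finite(nrm) && nrm > max_norm && nrm > 0) {
    scale <- max_norm / nrm
    grads <- lapply(grads, function(g) g * scale)
  }
  attr(grads, "norm") <- nrm
  grads
}

global_grad_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zeros_like <- function(params) lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
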