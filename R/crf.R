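# Linear-chain CRF: scoring, exact log-likelihood via forward-backward,
# Viterbi decoding, and an exhaustive-enumeration oracle used in tests.
#
# The pairwise factor at position i is f_i(y_prev, y, Z) =
# exp(score_i(y_prev, y)), with a virtual START label supplying the
# y_0 context of the first factor and no end factor.  Two
# parameterizations of score_i are supported:
#
#   * "factorized" (default): score_i(j, k) = T[j, k] + (E z_i + e_b)[k],
#     the standard BiLSTM-CRF form with one transition matrix and an
#     emission projection independent of the label pair;
#   * "pairwise": score_i(j, k) = W[j, k, ] . z_i + b[j, k], the literal
#     fully pairwise-by-emission form, at the cost of squaring the
#     parameter count.
#
# Both have the same functional shape (an affine function of z_i per
# ordered label pair) and share all downstream code through the n x (m+1)
# x m score tensor.  All dynamic programming is in log space.

#' Construct CRF head parameters
#'
#' @param m number of labels.
#' @param d emission (input feature) dimension.
#' @param form `"factorized"` or `"pairwise"` (see package vignette).
#' @param init `"zero"` or `"uniform"`; `seed`, `name` control uniform
#'   initialization.
#' @return list of parameter arrays; row `m + 1` of the transition slab is
#'   the virtual START label.
#' @export
crf_params <- function(m, d, form = c("factorized", "pairwise"),
                       init = c("zero", "uniform"), seed = 1L,
                       name = "crf") {
  form <- match.arg(form); init <- match.arg(init)
  mk <- function(suffix, dims)
    init_param(paste0(name, ".", suffix), dims, seed,
               dist = if (init == "zero") "zero" else "uniform")
  if (form == "factorized") {
    list(form = form, m = m, d = d,
         T = mk("T", c(m + 1L, m)), E = mk("E", c(m, d)),
         b = mk("b", m))
  } else {
    list(form = form, m = m, d = d,
         W = mk("W", c(m + 1L, m, d)), b = mk("b", c(m + 1L, m)))
  }
}

# Score tensor: array n x (m+1) x m; entry [i, j, k] is the log factor for
# transitioning from label j (m+1 = START) to label k at position i.
crf_score_tensor <- function(Z, head) {
  Z <- as.matrix(Z)
  n <- nrow(Z); m <- head$m
  S <- array(0, dim = c(n, m + 1L, m))
  if (head$form == "factorized") {
    em <- Z %*% t(head$E) + matrix(head$b, n, m, byrow = TRUE)  # n x m
    for (j in seq_len(m + 1L)) S[, j, ] <- em + matrix(head$T[j, ], n, m, byrow = TRUE)
  } else {
    Wm <- matrix(head$W, (m + 1L) * m, head$d)       # (m+1)m x d
    raw <- Z %*% t(Wm)                               # n x (m+1)m
    for (i in seq_len(n))
      S[i, , ] <- matrix(raw[i, ], m + 1L, m) + head$b
  }
  S
}

#' Log unnormalized score of a label sequence
#'
#' Sum over positions of the pairwise factor's exponent, with the virtual
#' START label as the context of position 1.
#'
#' @param Z emission matrix, one row per token.
#' @param y integer label sequence (1-based indices into the inventory).
#' @param head CRF parameters from [crf_params()].
#' @return scalar log score.
#' @export
score_sequence <- function(Z, y, head) {
  Z <- as.matrix(Z)
  n <- nrow(Z); m <- head$m
  if (length(y) != n) stop("|y| must equal nrow(Z)")
  if (any(y < 1L | y > m)) stop("label outside inventory")
  S <- crf_score_tensor(Z, head)
  prev <- m + 1L  # START
  total <- 0
  for (i in seq_len(n)) {
    total <- total + S[i, prev, y[i]]
    prev <- y[i]
  }
  total
}

#' Log partition function of the CRF
#'
#' Log of the sum over all m^n label sequences of the exponentiated
#' sequence score, computed by the forward algorithm in log space.
#'
#' @inheritParams score_sequence
#' @return scalar log partition value.
#' @export
crf_log_partition <- function(Z, head) {
  S <- crf_score_tensor(as.matrix(Z), head)
  logsumexp(crf_forward_alpha(S)[nrow(S), ])
}

# Forward variables: alpha[i, k] = log sum of scores of all prefixes ending
# in label k at position i.
crf_forward_alpha <- function(S) {
  n <- dim(S)[1]; m <- dim(S)[3]
  alpha <- matrix(0, n, m)
  alpha[1, ] <- S[1, m + 1L, ]
  if (n > 1) for (i in 2:n) {
    # alpha[i, k] = logsumexp_j(alpha[i-1, j] + S[i, j, k])
    M <- matrix(S[i, 1:m, ], m, m) + alpha[i - 1, ]  # [j, k]
    alpha[i, ] <- logsumexp_rows(t(M))
  }
  alpha
}

# Backward variables: beta[i, k] = log sum over completions given label k at i.
crf_backward_beta <- function(S) {
  n <- dim(S)[1]; m <- dim(S)[3]
  beta <- matrix(0, n, m)
  if (n > 1) for (i in (n - 1):1) {
    M <- matrix(S[i + 1, 1:m, ], m, m) +
      matrix(beta[i + 1, ], m, m, byrow = TRUE)
    beta[i, ] <- logsumexp_rows(M)
  }
  beta
}

#' Negative log-likelihood of a gold sequence under the CRF
#'
#' `J = log_partition - score_sequence(y_gold)`; non-negative for any
#' single sentence.  With `grad = TRUE` also returns analytic gradients
#' with respect to the head parameters and the emissions, computed from
#' forward-backward pairwise marginals.
#'
#' @inheritParams score_sequence
#' @param y_gold integer gold label sequence.
#' @param grad if TRUE, attach gradients.
#' @return list with `nll`, and when requested `grads` (named like the head
#'   parameter arrays) and `dZ` (same shape as `Z`).
#' @export
crf_nll <- function(Z, y_gold, head, grad = FALSE) {
  Z <- as.matrix(Z)
  n <- nrow(Z); m <- head$m
  S <- crf_score_tensor(Z, head)
  alpha <- crf_forward_alpha(S)
  logZ <- logsumexp(alpha[n, ])
  prev <- m + 1L; gold <- 0
  for (i in seq_len(n)) { gold <- gold + S[i, prev, y_gold[i]]; prev <- y_gold[i] }
  out <- list(nll = logZ - gold)
  if (!grad) return(out)

  beta <- crf_backward_beta(S)
  # dNLL / dS[i, j, k] = marginal p(y_{i-1}=j, y_i=k) - 1{gold}
  dS <- array(0, dim = dim(S))
  dS[1, m + 1L, ] <- exp(S[1, m + 1L, ] + beta[1, ] - logZ)
  if (n > 1) for (i in 2:n) {
    M <- matrix(alpha[i - 1, ], m, m) + matrix(S[i, 1:m, ], m, m) +
      matrix(beta[i, ], m, m, byrow = TRUE)
    dS[i, 1:m, ] <- exp(M - logZ)
  }
  prev <- m + 1L
  for (i in seq_len(n)) {
    dS[i, prev, y_gold[i]] <- dS[i, prev, y_gold[i]] - 1
    prev <- y_gold[i]
  }

  if (head$form == "factorized") {
    dT <- apply(dS, c(2, 3), sum)
    dem <- apply(dS, c(1, 3), sum); dim(dem) <- c(n, m)
    dE <- t(dem) %*% Z
    db <- colSums(dem)
    dZ <- dem %*% head$E
    out$grads <- list(T = dT, E = dE, b = db)
  } else {
    Wm <- matrix(head$W, (m + 1L) * m, head$d)
    dSm <- matrix(dS, n, (m + 1L) * m)        # row i = vec(dS[i, , ])
    dW <- array(t(dSm) %*% Z, dim = dim(head$W))
    db <- apply(dS, c(2, 3), sum)
    dZ <- dSm %*% Wm
    out$grads <- list(W = dW, b = db)
  }
  out$dZ <- dZ
  out
}

#' Viterbi decoding
#'
#' Returns the label sequence maximizing the sequence score and that score.
#' Ties are broken toward the lower label index at every backpointer step,
#' so decoding is deterministic.
#'
#' @inheritParams score_sequence
#' @return list with `path` (integer labels) and `score`.
#' @export
viterbi_decode <- function(Z, head) {
  Z <- as.matrix(Z)
  n <- nrow(Z); m <- head$m
  S <- crf_score_tensor(Z, head)
  delta <- matrix(-Inf, n, m)
  back <- matrix(0L, n, m)
  delta[1, ] <- S[1, m + 1L, ]
  if (n > 1) for (i in 2:n) {
    M <- matrix(delta[i - 1, ], m, m) + matrix(S[i, 1:m, ], m, m)
    back[i, ] <- apply(M, 2, which.max)  # first max = lowest index
    delta[i, ] <- M[cbind(back[i, ], seq_len(m))]
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (i in n:2) path[i - 1] <- back[i, path[i]]
  list(path = path, score = delta[n, path[n]])
}

#' Exhaustive enumeration oracle for the CRF
#'
#' Enumerates all m^n label sequences in lexicographic order, computing the
#' score of each, the exact log partition, and the argmax.  Used as the
#' independent reference for the dynamic-programming implementations;
#' refuses state spaces above one million sequences.
#'
#' @inheritParams score_sequence
#' @return list with `sequences` (matrix, one row per sequence), `scores`,
#'   `log_partition`, `argmax` (row index), `best_path`, `best_score`.
#' @export
crf_enumerate_oracle <- function(Z, head) {
  Z <- as.matrix(Z)
  n <- nrow(Z); m <- head$m
  if (m^n > 1e6) stop("state space too large for enumeration (m^n > 1e6)")
  # lexicographic order: last position varies fastest
  grids <- rev(lapply(seq_len(n), function(i) seq_len(m)))
  seqs <- as.matrix(rev(expand.grid(grids))[, seq_len(n), drop = FALSE])
  seqs <- matrix(as.integer(seqs), nrow(seqs), n)
  colnames(seqs) <- NULL
  scores <- vapply(seq_len(nrow(seqs)), function(r)
    score_sequence(Z, seqs[r, ], head), numeric(1))
  lp <- logsumexp(scores)
  am <- which.max(scores)  # first max = lexicographically smallest
  list(sequences = seqs, scores = scores, log_partition = lp,
       argmax = am, best_path = seqs[am, ], best_score = scores[am])
}
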