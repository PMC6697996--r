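# The enumeration oracle is the reference for every dynamic-programming
# path; closed forms cover the degenerate parameterizations.

random_head <- function(m, d, form, seed, scale = 4) {
  head <- crf_params(m, d, form = form, init = "uniform", seed = seed)
  for (nm in setdiff(names(head), c("form", "m", "d")))
    head[[nm]] <- head[[nm]] * scale
  head
}

test_that("score_sequence equals an independent term-by-term summation", {
  set.seed(11)
  for (form in c("factorized", "pairwise")) {
    m <- 3; d <- 4; n <- 4
    head <- random_head(m, d, form, 7)
    Z <- matrix(rnorm(n * d), n, d)
    y <- sample(m, n, replace = TRUE)
    # independent loop over the score-tensor definition
    S <- crossner:::crf_score_tensor(Z, head)
    expected <- 0; prev <- m + 1
    for (i in seq_len(n)) { expected <- expected + S[i, prev, y[i]]; prev <- y[i] }
    expect_equal(score_sequence(Z, y, head), expected, tolerance = 1e-12)
  }
  head <- crf_params(2, 3, init = "zero")
  Z <- matrix(rnorm(6), 2, 3)
  expect_equal(score_sequence(Z, c(1L, 2L), head), 0)
  expect_error(score_sequence(Z, c(1L, 5L), head), "inventory")
})

test_that("START biases alone route the length-one distribution", {
  head <- crf_params(2, 2, form = "pairwise", init = "zero")
  head$b[3, 1] <- 1   # b(START, A) = 1, b(START, B) = 0
  Z <- matrix(0, 1, 2)
  expect_equal(score_sequence(Z, 1L, head), 1)
  expect_equal(score_sequence(Z, 2L, head), 0)
})

test_that("log partition has the closed form n*log(m) at zero parameters", {
  for (m in 2:4) for (n in c(1, 3, 5)) {
    head <- crf_params(m, 3, init = "zero")
    Z <- matrix(rnorm(n * 3), n, 3)
    expect_equal(crf_log_partition(Z, head), n * log(m), tolerance = 1e-10)
  }
})

test_that("NLL matches closed forms and the enumerated probability", {
  # single-label inventory: p = 1, J = 0
  head1 <- random_head(1, 3, "factorized", 3)
  Z <- matrix(rnorm(9), 3, 3)
  expect_equal(crf_nll(Z, c(1L, 1L, 1L), head1)$nll, 0, tolerance = 1e-10)
  # zero params, m = 2, n = 2: J = log 4
  head <- crf_params(2, 3, init = "zero")
  expect_equal(crf_nll(matrix(0, 2, 3), c(1L, 2L), head)$nll, log(4),
               tolerance = 1e-12)
  set.seed(21)
  for (form in c("factorized", "pairwise")) for (rep in 1:5) {
    m <- sample(2:4, 1); n <- sample(2:5, 1); d <- 3
    head <- random_head(m, d, form, rep)
    Z <- matrix(rnorm(n * d), n, d)
    y <- sample(m, n, replace = TRUE)
    or <- crf_enumerate_oracle(Z, head)
    key <- which(apply(or$sequences, 1, function(s) all(s == y)))
    p <- exp(or$scores[key] - or$log_partition)
    expect_equal(crf_nll(Z, y, head)$nll, -log(p), tolerance = 1e-9)
  }
})

test_that("Viterbi agrees with enumeration and breaks ties lexicographically", {
  set.seed(5)
  for (form in c("factorized", "pairwise")) for (rep in 1:10) {
    m <- sample(2:4, 1); n <- sample(1:6, 1)
    head <- random_head(m, 3, form, 100 + rep)
    Z <- matrix(rnorm(n * 3), n, 3)
    or <- crf_enumerate_oracle(Z, head)
    v <- viterbi_decode(Z, head)
    expect_equal(v$path, unname(or$best_path))
    expect_equal(v$score, or$best_score, tolerance = 1e-9)
    expect_gte(v$score + 1e-12,
               score_sequence(Z, sample(m, n, replace = TRUE), head))
  }
  # total tie at zero parameters: lexicographically smallest sequence
  head <- crf_params(3, 2, init = "zero")
  v <- viterbi_decode(matrix(0, 4, 2), head)
  expect_equal(v$path, rep(1L, 4))
  # emission-dominant: per-position argmax
  head <- crf_params(3, 3, init = "zero")
  head$E <- diag(3) * 10
  Z <- rbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))
  expect_equal(viterbi_decode(Z, head)$path, c(1L, 3L, 2L))
})

test_that("enumerated probabilities normalize and the oracle guards its size", {
  set.seed(9)
  for (rep in 1:10) {
    m <- sample(2:4, 1); n <- sample(1:6, 1)
    head <- random_head(m, 3, sample(c("factorized", "pairwise"), 1), rep)
    or <- crf_enumerate_oracle(matrix(rnorm(n * 3), n, 3), head)
    expect_equal(sum(exp(or$scores - or$log_partition)), 1,
                 tolerance = 1e-10)
  }
  head <- crf_params(4, 2, init = "zero")
  expect_error(crf_enumerate_oracle(matrix(0, 12, 2), head), "too large")
})

test_that("probabilities are invariant to a constant shift of position biases", {
  set.seed(13)
  head <- random_head(3, 3, "pairwise", 44)
  Z <- matrix(rnorm(12), 4, 3)
  y <- c(2L, 1L, 3L, 3L)
  nll0 <- crf_nll(Z, y, head)$nll
  head$b <- head$b + 2.5   # same constant into every factor at every position
  expect_equal(crf_nll(Z, y, head)$nll, nll0, tolerance = 1e-9)
})

test_that("NLL gradients match finite differences on toys", {
  set.seed(17)
  eps <- 1e-6
  for (form in c("factorized", "pairwise")) {
    m <- 3; n <- 4; d <- 3
    head <- random_head(m, d, form, 55)
    Z <- matrix(rnorm(n * d), n, d)
    y <- sample(m, n, replace = TRUE)
    res <- crf_nll(Z, y, head, grad = TRUE)
    for (nm in names(res$grads)) {
      for (ii in sample(length(res$grads[[nm]]),
                        min(5, length(res$grads[[nm]])))) {
        h2 <- head; h2[[nm]][ii] <- h2[[nm]][ii] + eps
        f1 <- crf_nll(Z, y, h2)$nll
        h2[[nm]][ii] <- h2[[nm]][ii] - 2 * eps
        f0 <- crf_nll(Z, y, h2)$nll
        num <- (f1 - f0) / (2 * eps)
        expect_equal(res$grads[[nm]][ii], num,
                     tolerance = 1e-4 * max(1, abs(num)))
      }
    }
    for (ii in sample(length(Z), 4)) {
      Z2 <- Z; Z2[ii] <- Z2[ii] + eps
      f1 <- crf_nll(Z2, y, head)$nll
      Z2[ii] <- Z2[ii] - 2 * eps
      f0 <- crf_nll(Z2, y, head)$nll
      expect_equal(res$dZ[ii], (f1 - f0) / (2 * eps), tolerance = 1e-4)
    }
  }
})
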