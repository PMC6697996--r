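# Architecture composition, the auxiliary losses and their algebra.

test_that("emission dimensions follow the architecture", {
  pair <- small_pair()
  vocab <- build_vocab(list(pair$main, pair$aux))
  cfg <- micro_config()
  sents <- pair$main$splits$train[1:2]
  dims <- c(stm = 4L, fs = 4L, sp = 8L, adv = 8L, cs = 8L)  # proj = 4
  for (arch in names(dims)) {
    m <- build_model(arch, vocab, cfg)
    fw <- model_forward(m, sents, d = 1, decode = TRUE)
    expect_equal(dim(fw$emissions)[3], dims[[arch]])
    expect_length(fw$tags, 2)
    expect_true(all(unlist(fw$tags) %in% pair$main$scheme$labels))
    # dropout off at evaluation: repeatable emissions
    fw2 <- model_forward(m, sents, d = 1, decode = FALSE)
    expect_identical(fw$emissions, fw2$emissions)
  }
  # single-token sentence processes end to end
  m <- build_model("stm", vocab, cfg)
  one <- list(sent("gene", "B-GENE"))
  expect_length(model_forward(m, one, d = 1)$tags[[1]], 1)
})

test_that("dataset routing activates exactly one CRF head", {
  pair <- small_pair()
  vocab <- build_vocab(list(pair$main, pair$aux))
  m <- build_model("fs", vocab, micro_config())
  b1 <- crossner:::make_batch(pair$main$splits$train[1:2], vocab,
                              pair$main$name)
  r1 <- crossner:::compute_batch(m, b1, d = 1, train = FALSE, grad = TRUE)
  expect_null(r1$grads$crf2)          # ignored head gets no gradient
  expect_false(is.null(r1$grads$crf1))
  b2 <- crossner:::make_batch(pair$aux$splits$train[1:2], vocab,
                              pair$aux$name)
  r2 <- crossner:::compute_batch(m, b2, d = 2, train = FALSE, grad = TRUE)
  expect_null(r2$grads$crf1)
  # the shared encoder receives gradients from both batches
  expect_gt(crossner:::global_grad_norm(
    crossner:::collect_leaves(r1$grads$enc)), 0)
  expect_gt(crossner:::global_grad_norm(
    crossner:::collect_leaves(r2$grads$enc)), 0)
  # sp: the other private encoder is not touched
  msp <- build_model("sp", vocab, micro_config())
  rsp <- crossner:::compute_batch(msp, b1, d = 1, train = FALSE,
                                  grad = TRUE)
  expect_null(rsp$grads$enc_p2)
  expect_false(is.null(rsp$grads$enc_p1))
})

test_that("diff_loss is the squared Frobenius norm of the cross-product", {
  set.seed(4)
  S <- qr.Q(qr(matrix(rnorm(12), 4, 3)))   # orthonormal columns
  P <- matrix(0, 4, 3)
  P[, 1] <- S[, 1]
  # S orthogonal to P gives zero
  null_comp <- diag(4) - S %*% t(S)
  P_orth <- null_comp %*% matrix(rnorm(12), 4, 3)
  expect_equal(diff_loss(S, P_orth), 0, tolerance = 1e-20)
  # quadratic scaling in S
  A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(12), 4, 3)
  expect_equal(diff_loss(3 * A, B), 9 * diff_loss(A, B), tolerance = 1e-10)
  # equals an explicit double loop
  S2 <- matrix(rnorm(6), 3, 2); P1 <- matrix(rnorm(6), 3, 2)
  P2 <- matrix(rnorm(6), 3, 2)
  loop <- 0
  for (P in list(P1, P2)) {
    M <- t(S2) %*% P
    for (i in 1:2) for (j in 1:2) loop <- loop + M[i, j]^2
  }
  expect_equal(diff_loss(S2, P1, P2), loop, tolerance = 1e-12)
  expect_gte(diff_loss(S2, P1), 0)
  expect_error(diff_loss(S2, matrix(0, 2, 2)), "shape")
})

test_that("discriminator is a softmax with the usual invariances", {
  disc <- list(W = matrix(0, 2, 4), b = c(0, 0))
  expect_equal(discriminator_forward(rnorm(4), disc),
               matrix(0.5, 1, 2))
  set.seed(6)
  disc <- list(W = matrix(rnorm(8), 2, 4), b = rnorm(2))
  s <- rnorm(4)
  p1 <- discriminator_forward(s, disc)
  expect_equal(sum(p1), 1, tolerance = 1e-12)
  logits <- as.vector(disc$W %*% s + disc$b)
  expect_equal(as.vector(p1), exp(logits) / sum(exp(logits)),
               tolerance = 1e-12)
  disc2 <- disc; disc2$b <- disc$b + 7   # constant logit shift
  expect_equal(discriminator_forward(s, disc2), p1, tolerance = 1e-12)
})

test_that("adversarial loss is log K for a zero or uniform discriminator", {
  disc <- list(W = matrix(0, 2, 5), b = c(0, 0))
  s_T <- matrix(rnorm(15), 3, 5)
  expect_equal(adversarial_loss(s_T, 1, disc)$loss, log(2),
               tolerance = 1e-12)
  expect_equal(adversarial_loss(s_T, 2, disc)$loss, log(2),
               tolerance = 1e-12)
})

test_that("gradient reversal is the identity forward and negation backward", {
  x <- c(1.5, -2)
  y <- gradient_reversal(x)
  expect_equal(as.vector(y), x)
  # f(grl(x)) = x^2 at x = 3: upstream gradient 2x = 6, reversed -6
  x <- 3
  y <- gradient_reversal(x)
  expect_equal(grl_gradient(y, 2 * as.vector(y)), -6)
  # double reversal restores the gradient
  y2 <- gradient_reversal(y)
  expect_equal(grl_gradient(y2, 2 * as.vector(y2)), 6)
})

test_that("gated interaction matches its closed forms and a hand case", {
  set.seed(10)
  P1 <- matrix(rnorm(8), 4, 2); P2 <- matrix(rnorm(8), 4, 2)
  gate0 <- list(W12 = matrix(0, 2, 2), W21 = matrix(0, 2, 2),
                b12 = c(0, 0), b21 = c(0, 0))
  expect_equal(gated_interaction(P1, P2, gate0, 1), 0.5 * P1)
  expect_equal(gated_interaction(P1, P2, gate0, 2), 0.5 * P2)
  gate_sat <- gate0; gate_sat$b21 <- c(20, 20)
  expect_equal(gated_interaction(P1, P2, gate_sat, 1), P1,
               tolerance = 1e-8)
  # two-dimensional hand evaluation
  gate <- list(W12 = matrix(c(1, 0, -1, 2), 2, 2),
               W21 = matrix(c(0.5, 1, 0, -0.5), 2, 2),
               b12 = c(0.1, -0.2), b21 = c(0, 0.3))
  p1 <- c(1, -1); p2 <- c(0.5, 2)
  sg <- function(z) 1 / (1 + exp(-z))
  a1 <- sg(gate$W21 %*% p2 + gate$b21)
  expect_equal(as.vector(gated_interaction(rbind(p1), rbind(p2), gate, 1)),
               p1 * as.vector(a1), tolerance = 1e-12)
  a2 <- sg(gate$W12 %*% p1 + gate$b12)
  expect_equal(as.vector(gated_interaction(rbind(p1), rbind(p2), gate, 2)),
               p2 * as.vector(a2), tolerance = 1e-12)
  expect_error(gated_interaction(P1, matrix(0, 2, 2), gate0, 1), "shape")
})

test_that("cross-sharing output is gated-private next to shared features", {
  pair <- small_pair()
  vocab <- build_vocab(list(pair$main, pair$aux))
  cfg <- micro_config()
  m <- build_model("cs", vocab, cfg)
  # zero the gate and the shared projection: V = (0.5 * P1) (+) 0 for D1
  m$params$gate$W12[] <- 0; m$params$gate$W21[] <- 0
  m$params$gate$b12[] <- 0; m$params$gate$b21[] <- 0
  m$params$enc_shared$W_p[] <- 0; m$params$enc_shared$b_p[] <- 0
  sents <- pair$main$splits$train[1:2]
  fw <- model_forward(m, sents, d = 1, decode = FALSE)
  proj <- cfg$proj
  expect_equal(dim(fw$emissions)[3], 2L * proj)
  expect_equal(fw$emissions[, , proj + seq_len(proj)],
               array(0, dim = dim(fw$emissions[, , seq_len(proj)])))
  mp <- m; mp$params$gate <- NULL
  # private-only forward: compare gated half against 0.5 * P1 directly
  batch <- crossner:::make_batch(sents, vocab, pair$main$name)
  enc <- bilstm_encode(
    crossner:::compute_batch(m, batch, d = 1, train = FALSE,
                             grad = FALSE)$encoders$enc_p1$cache$Xd,
    batch$mask, m$params$enc_p1)
  expect_equal(fw$emissions[, , seq_len(proj)], 0.5 * enc$P,
               tolerance = 1e-10)
  # gradients reach the other private encoder through the gate
  m2 <- build_model("cs", vocab, cfg)
  res <- crossner:::compute_batch(m2, batch, d = 1, train = FALSE,
                                  grad = TRUE)
  expect_gt(crossner:::global_grad_norm(
    crossner:::collect_leaves(res$grads$enc_p2)), 0)
})

test_that("total loss is the weighted sum of its components", {
  expect_equal(total_loss(1, 2, 3, alpha = 0.1, beta = 0.01), 1.23)
  expect_equal(total_loss(5, 100, 100, alpha = 0, beta = 0), 5)
})

test_that("parameter counts obey the construction algebra", {
  pair <- small_pair()
  vocab <- build_vocab(list(pair$main, pair$aux))
  cfg <- micro_config()
  n <- vapply(c("stm", "fs", "sp", "adv", "cs"), function(a)
    count_parameters(build_model(a, vocab, cfg)), integer(1))
  proj <- cfg$proj
  # cross-sharing adds exactly the gate unit over shared-private
  expect_equal(n[["cs"]] - n[["sp"]], 2L * (proj^2 + proj))
  # fully-shared adds exactly one CRF head over the baseline
  m_fs <- build_model("fs", vocab, cfg)
  crf2_size <- sum(vapply(crossner:::collect_leaves(m_fs$params$crf2),
                          length, integer(1)))
  expect_equal(n[["fs"]] - n[["stm"]], crf2_size)
  # adversarial adds exactly the discriminator over shared-private
  expect_equal(n[["adv"]] - n[["sp"]], 2L * proj + 2L)
  bd <- param_breakdown(m_fs)
  expect_equal(sum(bd), n[["fs"]])
})

test_that("adversarial model with zero weights reproduces shared-private exactly", {
  pair <- small_pair()
  cfg_t <- train_config(epochs = 2, batch_size = 8, seed = 33,
                        alpha = 0, beta = 0)
  mc <- micro_config()
  f_sp <- train(pair$main, pair$aux, "sp", cfg_t, mc)
  f_adv <- train(pair$main, pair$aux, "adv", cfg_t, mc)
  expect_identical(f_sp$history$L_task, f_adv$history$L_task)
  expect_identical(f_sp$history$dev_f1_main, f_adv$history$dev_f1_main)
  # every tensor they share is bit-identical after training
  sp_leaves <- crossner:::collect_leaves(f_sp$model$params)
  adv_leaves <- crossner:::collect_leaves(f_adv$model$params)
  for (nm in names(sp_leaves))
    expect_identical(sp_leaves[[nm]], adv_leaves[[nm]])
})

test_that("all losses stay finite and non-negative where required", {
  pair <- small_pair()
  vocab <- build_vocab(list(pair$main, pair$aux))
  for (arch in c("sp", "adv", "cs")) {
    m <- build_model(arch, vocab, micro_config(seed = 17))
    batch <- crossner:::make_batch(pair$main$splits$train[1:3], vocab,
                                   pair$main$name)
    r <- crossner:::compute_batch(m, batch, d = 1, train = FALSE,
                                  grad = FALSE, alpha = 0.1, beta = 0.01)
    expect_true(is.finite(r$loss))
    expect_gte(r$breakdown$L_diff, 0)
    expect_gte(r$breakdown$L_task, 0)
  }
})
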