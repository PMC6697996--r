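# Composition of the five architectures: the single-task baseline (stm),
# the fully-shared (fs), shared-private (sp), adversarial (adv) and
# cross-sharing (cs) multi-task models, together with their losses and
# analytic gradients.
#
# Emission layouts fed to the CRF heads:
#   stm / fs : encoder projection            (dim proj)
#   sp  / adv: [private | shared]            (dim 2 * proj)
#   cs       : [gated   | shared]            (dim 2 * proj)

ARCHITECTURES <- c("stm", "fs", "sp", "adv", "cs")

# names inside parameter lists that are metadata, not trainable tensors
META_FIELDS <- c("hidden", "proj", "form", "m", "d", "d_c", "n_filters",
                 "l_f")

#' Default model hyperparameters
#'
#' The defaults mirror the reference configuration: 100-dimensional word
#' vectors, 30-dimensional character embeddings with 30 width-3 filters,
#' hidden size 256 per LSTM direction projected to 128, dropout 0.5
#' everywhere, and the factorized CRF parameterization.
#'
#' @param d_w,d_c,n_filters,l_f,hidden,proj,dropout,crf_form,seed see
#'   descriptions above.
#' @return named list of hyperparameters.
#' @export
model_config <- function(d_w = 100L, d_c = 30L, n_filters = 30L, l_f = 3L,
                         hidden = 256L, proj = 128L, dropout = 0.5,
                         crf_form = c("factorized", "pairwise"), seed = 1L) {
  list(d_w = d_w, d_c = d_c, n_filters = n_filters, l_f = l_f,
       hidden = hidden, proj = proj, dropout = dropout,
       crf_form = match.arg(crf_form), seed = as.integer(seed))
}

#' Build a model
#'
#' Constructs all trainable tensors for one architecture over the tag
#' inventories of a vocabulary.  Each tensor is initialized from a seed
#' derived from its own name and `config$seed`, so two models sharing a
#' tensor name initialize that tensor identically regardless of what else
#' they contain.
#'
#' @param architecture one of `"stm"`, `"fs"`, `"sp"`, `"adv"`, `"cs"`.
#' @param vocab a [build_vocab()] vocabulary; `stm` uses its first tagset,
#'   the multi-task architectures need exactly two.
#' @param config from [model_config()].
#' @param pretrained optional named list of word vectors (see
#'   [load_pretrained_vectors()]); matching rows (exact, then lowercase)
#'   seed the word embedding, all word vectors remain trainable.
#' @return object of class `ner_model`.
#' @export
build_model <- function(architecture, vocab, config = model_config(),
                        pretrained = NULL) {
  architecture <- match.arg(architecture, ARCHITECTURES)
  dsets <- names(vocab$tag_index)
  need <- if (architecture == "stm") 1L else 2L
  if (length(dsets) < need)
    stop("architecture '", architecture, "' needs ", need, " tagset(s)")
  dsets <- dsets[seq_len(min(length(dsets), 2L))]
  seed <- config$seed
  nv <- length(vocab$word_index); nc <- length(vocab$char_index)
  emb <- init_param("word_emb", c(nv, config$d_w), seed,
                    range = sqrt(3 / config$d_w))
  emb[1, ] <- 0  # PAD
  if (!is.null(pretrained)) {
    keys <- names(vocab$word_index)
    for (i in seq_along(keys)) {
      v <- pretrained[[keys[i]]] %||% pretrained[[tolower(keys[i])]]
      if (!is.null(v)) {
        if (length(v) != config$d_w)
          stop("configuration error: pretrained dim ", length(v),
               " != d_w ", config$d_w)
        emb[i, ] <- v
      }
    }
    emb[1, ] <- 0
  }
  d_in <- config$d_w + config$n_filters
  params <- list(
    word_emb = emb,
    cnn = char_cnn_params(nc, config$d_c, config$n_filters, config$l_f,
                          seed = seed))
  shared_private <- architecture %in% c("sp", "adv", "cs")
  d_em <- if (shared_private) 2L * config$proj else config$proj
  if (shared_private) {
    params$enc_shared <- bilstm_params(d_in, config$hidden, config$proj,
                                       seed, "enc_shared")
    params$enc_p1 <- bilstm_params(d_in, config$hidden, config$proj,
                                   seed, "enc_p1")
    params$enc_p2 <- bilstm_params(d_in, config$hidden, config$proj,
                                   seed, "enc_p2")
  } else {
    params$enc <- bilstm_params(d_in, config$hidden, config$proj, seed,
                                "enc")
  }
  params$crf1 <- crf_params(length(vocab$tag_index[[dsets[1]]]), d_em,
                            form = config$crf_form, init = "uniform",
                            seed = seed, name = "crf1")
  if (architecture != "stm")
    params$crf2 <- crf_params(length(vocab$tag_index[[dsets[2]]]), d_em,
                              form = config$crf_form, init = "uniform",
                              seed = seed, name = "crf2")
  if (architecture == "cs")
    params$gate <- list(
      W12 = init_param("gate.W12", c(config$proj, config$proj), seed),
      W21 = init_param("gate.W21", c(config$proj, config$proj), seed),
      b12 = init_param("gate.b12", config$proj, seed),
      b21 = init_param("gate.b21", config$proj, seed))
  if (architecture == "adv")
    params$disc <- list(W = init_param("disc.W", c(2L, config$proj), seed),
                        b = init_param("disc.b", 2L, seed))
  structure(list(arch = architecture, config = config, vocab = vocab,
                 datasets = dsets, params = params),
            class = "ner_model")
}

#' @export
print.ner_model <- function(x, ...) {
  cat("<ner_model> ", x$arch, " | datasets: ",
      paste(x$datasets, collapse = ", "),
      " | parameters: ", count_parameters(x), "\n", sep = "")
  invisible(x)
}

# Recursively collect trainable leaves into a flat named list.
collect_leaves <- function(x, prefix = "") {
  out <- list()
  nms <- names(x) %||% as.character(seq_along(x))
  for (k in seq_along(x)) {
    nm <- if (nzchar(nms[k])) nms[k] else as.character(k)
    full <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    v <- x[[k]]
    if (nm %in% META_FIELDS) next
    if (is.list(v)) out <- c(out, collect_leaves(v, full))
    else if (is.numeric(v)) out[[full]] <- v
  }
  out
}

#' Count trainable scalars of a model
#'
#' Counts every entry of every parameter tensor (metadata fields such as
#' dimensions excluded).  See [param_breakdown()] for an itemized view;
#' whether embedding tables are included in published totals varies, so the
#' breakdown reports each component separately.
#'
#' @param model a [build_model()] model.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  sum(vapply(collect_leaves(model$params), length, integer(1)))
}

#' Itemized parameter counts per component
#'
#' @param model a [build_model()] model.
#' @return named integer vector, one entry per top-level component.
#' @export
param_breakdown <- function(model) {
  comps <- names(model$params)
  stats::setNames(vapply(comps, function(cc)
    sum(vapply(collect_leaves(model$params[[cc]]), length, integer(1))),
    integer(1)), comps)
}

#' Squared-Frobenius orthogonality loss between shared and private features
#'
#' `L_diff = sum_k || S^T P_k ||_F^2`, the squared Frobenius norm of the
#' cross-product between the time-stacked shared output matrix and each
#' private output matrix.  Minimizing it pushes shared and private
#' encoders toward orthogonal feature subspaces.  Always non-negative.
#'
#' @param S matrix `time x proj` of shared-encoder outputs.
#' @param P1,P2 private-output matrices of the same shape; either may be
#'   `NULL` (single-source batches only see their own private encoder).
#' @return scalar loss.
#' @export
diff_loss <- function(S, P1 = NULL, P2 = NULL) {
  tot <- 0
  for (P in list(P1, P2)) {
    if (is.null(P)) next
    if (!all(dim(P) == dim(S))) stop("shape mismatch in diff_loss")
    M <- t(S) %*% P
    tot <- tot + sum(M * M)
  }
  tot
}

# gradient of diff_loss w.r.t. S and one P
diff_loss_grads <- function(S, P) {
  M <- t(S) %*% P
  list(dS = 2 * P %*% t(M), dP = 2 * S %*% M)
}

#' Dataset discriminator
#'
#' Softmax classifier over the shared-encoder sentence summary:
#' `D(s) = softmax(W s + b)`.
#'
#' @param s summary vector (or matrix of row vectors).
#' @param disc list with `W` (`K x proj`) and `b` (length `K`).
#' @return probability vector(s) summing to 1.
#' @export
discriminator_forward <- function(s, disc) {
  s <- rbind(s)
  if (ncol(s) != ncol(disc$W)) stop("shape mismatch in discriminator")
  logits <- s %*% t(disc$W) + rep(disc$b, each = nrow(s))
  dimnames(logits) <- NULL
  ex <- exp(logits - apply(logits, 1, max))
  ex / rowSums(ex)
}

#' Adversarial dataset-confusion loss
#'
#' Cross-entropy of the discriminator against the true dataset label,
#' averaged over the batch.  During training the discriminator parameters
#' receive the standard minimizing gradient while the gradient flowing
#' back into the shared encoder passes through [gradient_reversal()], so a
#' single backward pass trains the discriminator to identify the source
#' dataset and the shared encoder to confuse it.
#'
#' @param s_T matrix `B x proj` of shared sentence summaries (final real
#'   time step of the projected shared output).
#' @param k true dataset index (1 or 2) of this single-source batch.
#' @param disc discriminator parameters.
#' @param grad if TRUE, return gradients: `dW`, `db` (unreversed,
#'   discriminator side) and `ds` (unreversed; the caller negates it for
#'   the encoder side).
#' @return list with `loss` and optionally the gradients.
#' @export
adversarial_loss <- function(s_T, k, disc, grad = FALSE) {
  s_T <- rbind(s_T)
  B <- nrow(s_T)
  probs <- discriminator_forward(s_T, disc)
  loss <- -mean(log(pmax(probs[, k], 1e-300)))
  if (!grad) return(list(loss = loss))
  dlogits <- probs
  dlogits[, k] <- dlogits[, k] - 1
  dlogits <- dlogits / B
  list(loss = loss,
       dW = t(dlogits) %*% s_T,
       db = colSums(dlogits),
       ds = dlogits %*% disc$W)
}

#' Gradient reversal operation
#'
#' Identity in the forward direction; the backward-flowing gradient is
#' multiplied by -1.  The accumulated multiplier is carried in the `"grl"`
#' attribute, so composing two reversals restores the original gradient.
#' Use [grl_gradient()] to apply the multiplier to an upstream gradient.
#'
#' @param x any numeric value.
#' @return `x` unchanged, with its reversal multiplier negated.
#' @export
gradient_reversal <- function(x) {
  mult <- attr(x, "grl") %||% 1
  attr(x, "grl") <- -mult
  x
}

#' Apply the reversal multiplier of a forward value to its gradient
#'
#' @param y a value that passed through [gradient_reversal()] zero or more
#'   times.
#' @param dy the gradient arriving at `y`.
#' @return the gradient to propagate further back.
#' @export
grl_gradient <- function(y, dy) {
  dy * (attr(y, "grl") %||% 1)
}

#' Weighted total loss
#'
#' `L = L_task + alpha * L_adv + beta * L_diff`.
#'
#' @param L_task,L_adv,L_diff loss components.
#' @param alpha,beta weights.
#' @return scalar total.
#' @export
total_loss <- function(L_task, L_adv = 0, L_diff = 0, alpha = 0, beta = 0) {
  L_task + alpha * L_adv + beta * L_diff
}

#' Gated interaction unit
#'
#' Each private representation is modulated elementwise by a sigmoid gate
#' computed from the other dataset's private representation:
#' `G1 = P1 * sigmoid(W21 P2 + b21)`, `G2 = P2 * sigmoid(W12 P1 + b12)`;
#' the source dataset selects which of the two is emitted.  The gate
#' parameters are shared across time: the matrices act on each per-token
#' vector.
#'
#' @param P1,P2 matrices `time x proj` of private outputs (rows are token
#'   vectors).
#' @param gate list with `W12`, `W21` (`proj x proj`) and `b12`, `b21`.
#' @param d source dataset index (1 or 2).
#' @return matrix `G` of the same shape as the private outputs.
#' @export
gated_interaction <- function(P1, P2, gate, d) {
  P1 <- rbind(P1); P2 <- rbind(P2)
  if (!all(dim(P1) == dim(P2))) stop("shape mismatch in gated_interaction")
  if (d == 1L) {
    A <- P2 %*% t(gate$W21) + rep(gate$b21, each = nrow(P2))
    P1 * sigmoid(A)
  } else {
    A <- P1 %*% t(gate$W12) + rep(gate$b12, each = nrow(P1))
    P2 * sigmoid(A)
  }
}

# Forward + optional backward over one single-source padded batch.
#
# batch: list(word_ids B x T, mask B x T, lens, char_ids, char_lens,
#             real_idx (flat indices of real tokens, column-major), tags
#             list of integer vectors)
# d: dataset index (1 or 2)
# Returns loss breakdown, per-sentence decoded input (optionally), and
# nested gradients mirroring model$params.
compute_batch <- function(model, batch, d = 1L, train = TRUE, grad = TRUE,
                          alpha = 0, beta = 0, decode = FALSE) {
  p <- model$params
  cfg <- model$config
  arch <- model$arch
  if (arch == "stm" && d != 1L) stop("unknown dataset id for stm")
  B <- nrow(batch$word_ids); TT <- ncol(batch$word_ids)
  dr <- cfg$dropout

  ## ---- embeddings ----
  w_ids <- as.vector(batch$word_ids)              # column-major, b fastest
  Xw <- p$word_emb[w_ids, , drop = FALSE]         # (B*T) x d_w
  n_real <- length(batch$real_idx)
  Lp <- ncol(batch$char_ids) + 2L * (cfg$l_f - 1L)
  cnn_mask <- dropout_mask(c(n_real * Lp, cfg$d_c), dr, train)
  cnn_fw <- char_cnn_forward(batch$char_ids, batch$char_lens, p$cnn,
                             drop_mask = cnn_mask)
  Xc <- matrix(0, B * TT, cfg$n_filters)
  Xc[batch$real_idx, ] <- cnn_fw$r
  X <- array(cbind(Xw, Xc), dim = c(B, TT, cfg$d_w + cfg$n_filters))

  ## ---- encoders ----
  shared_private <- arch %in% c("sp", "adv", "cs")
  encs <- list()
  if (shared_private) {
    encs$enc_shared <- bilstm_encode(X, batch$mask, p$enc_shared, dr, train)
    if (arch == "cs") {
      encs$enc_p1 <- bilstm_encode(X, batch$mask, p$enc_p1, dr, train)
      encs$enc_p2 <- bilstm_encode(X, batch$mask, p$enc_p2, dr, train)
    } else {
      pk <- if (d == 1L) "enc_p1" else "enc_p2"
      encs[[pk]] <- bilstm_encode(X, batch$mask, p[[pk]], dr, train)
    }
  } else {
    encs$enc <- bilstm_encode(X, batch$mask, p$enc, dr, train)
  }

  ## ---- composition ----
  proj <- cfg$proj
  gate_cache <- NULL
  if (arch %in% c("stm", "fs")) {
    EM <- encs$enc$P
  } else if (arch %in% c("sp", "adv")) {
    pk <- if (d == 1L) "enc_p1" else "enc_p2"
    EM <- array(0, dim = c(B, TT, 2L * proj))
    EM[, , seq_len(proj)] <- encs[[pk]]$P
    EM[, , proj + seq_len(proj)] <- encs$enc_shared$P
  } else {  # cs
    P1m <- matrix(encs$enc_p1$P, B * TT, proj)
    P2m <- matrix(encs$enc_p2$P, B * TT, proj)
    if (d == 1L) {
      A <- P2m %*% t(p$gate$W21) + rep(p$gate$b21, each = B * TT)
      sg <- sigmoid(A)
      Gm <- P1m * sg
    } else {
      A <- P1m %*% t(p$gate$W12) + rep(p$gate$b12, each = B * TT)
      sg <- sigmoid(A)
      Gm <- P2m * sg
    }
    gate_cache <- list(P1m = P1m, P2m = P2m, sg = sg)
    EM <- array(0, dim = c(B, TT, 2L * proj))
    EM[, , seq_len(proj)] <- array(Gm, dim = c(B, TT, proj))
    EM[, , proj + seq_len(proj)] <- encs$enc_shared$P
  }

  ## ---- CRF task loss (sum over sentences) ----
  head_name <- if (d == 1L) "crf1" else "crf2"
  head <- p[[head_name]]
  L_task <- 0
  dEM <- if (grad) array(0, dim = dim(EM)) else NULL
  crf_grads <- NULL
  paths <- if (decode) vector("list", B) else NULL
  for (b in seq_len(B)) {
    len <- batch$lens[b]
    Z <- matrix(EM[b, seq_len(len), ], nrow = len)
    if (decode) paths[[b]] <- viterbi_decode(Z, head)$path
    nl <- crf_nll(Z, batch$tags[[b]], head, grad = grad)
    L_task <- L_task + nl$nll
    if (grad) {
      dEM[b, seq_len(len), ] <- nl$dZ
      if (is.null(crf_grads)) crf_grads <- nl$grads
      else for (nm in names(crf_grads))
        crf_grads[[nm]] <- crf_grads[[nm]] + nl$grads[[nm]]
    }
  }

  ## ---- auxiliary losses (adversarial architecture) ----
  L_adv <- 0; L_diff <- 0
  adv_info <- NULL; diff_info <- NULL
  if (arch == "adv") {
    Sp <- encs$enc_shared$P_pre
    s_T <- matrix(0, B, proj)
    for (b in seq_len(B)) s_T[b, ] <- Sp[b, batch$lens[b], ]
    al <- adversarial_loss(s_T, d, p$disc, grad = grad)
    L_adv <- al$loss
    adv_info <- c(al, list(s_T = s_T))
    pk <- if (d == 1L) "enc_p1" else "enc_p2"
    Pp <- encs[[pk]]$P_pre
    diff_info <- vector("list", B)
    for (b in seq_len(B)) {
      len <- batch$lens[b]
      Sm <- matrix(Sp[b, seq_len(len), ], nrow = len)
      Pm <- matrix(Pp[b, seq_len(len), ], nrow = len)
      L_diff <- L_diff + diff_loss(Sm, Pm)
      if (grad) diff_info[[b]] <- diff_loss_grads(Sm, Pm)
    }
    L_diff <- L_diff / B
  }
  L <- total_loss(L_task, L_adv, L_diff, alpha, beta)
  out <- list(loss = L,
              breakdown = list(L_task = L_task, L_adv = L_adv,
                               L_diff = L_diff, alpha = alpha, beta = beta,
                               total = L),
              paths = paths, emissions = EM, encoders = encs)
  if (!grad) return(out)

  ## ---- backward ----
  grads <- list()
  grads[[head_name]] <- crf_grads

  # split emission gradient into encoder output gradients
  dP_by_enc <- list(); dPpre_by_enc <- list()
  if (arch %in% c("stm", "fs")) {
    dP_by_enc$enc <- dEM
  } else if (arch %in% c("sp", "adv")) {
    pk <- if (d == 1L) "enc_p1" else "enc_p2"
    dP_by_enc[[pk]] <- dEM[, , seq_len(proj), drop = FALSE]
    dP_by_enc$enc_shared <- dEM[, , proj + seq_len(proj), drop = FALSE]
  } else {  # cs: through the gate
    dGm <- matrix(dEM[, , seq_len(proj), drop = FALSE], B * TT, proj)
    dP_by_enc$enc_shared <- dEM[, , proj + seq_len(proj), drop = FALSE]
    sg <- gate_cache$sg
    if (d == 1L) {
      dP1m <- dGm * sg
      dA <- dGm * gate_cache$P1m * sg * (1 - sg)
      grads$gate <- list(W12 = array(0, dim = dim(p$gate$W12)),
                         W21 = t(dA) %*% gate_cache$P2m,
                         b12 = numeric(proj), b21 = colSums(dA))
      dP2m <- dA %*% p$gate$W21
    } else {
      dP2m <- dGm * sg
      dA <- dGm * gate_cache$P2m * sg * (1 - sg)
      grads$gate <- list(W12 = t(dA) %*% gate_cache$P1m,
                         W21 = array(0, dim = dim(p$gate$W21)),
                         b12 = colSums(dA), b21 = numeric(proj))
      dP1m <- dA %*% p$gate$W12
    }
    dP_by_enc$enc_p1 <- array(dP1m, dim = c(B, TT, proj))
    dP_by_enc$enc_p2 <- array(dP2m, dim = c(B, TT, proj))
  }

  # adversarial + orthogonality gradients enter through P_pre
  if (arch == "adv") {
    dSpre <- array(0, dim = c(B, TT, proj))
    pk <- if (d == 1L) "enc_p1" else "enc_p2"
    dPpre_priv <- array(0, dim = c(B, TT, proj))
    if (alpha != 0) {
      # gradient reversal: encoder side receives -alpha * standard grad
      ds_rev <- grl_gradient(gradient_reversal(0), adv_info$ds) * alpha
      for (b in seq_len(B))
        dSpre[b, batch$lens[b], ] <- dSpre[b, batch$lens[b], ] + ds_rev[b, ]
      grads$disc <- list(W = alpha * adv_info$dW, b = alpha * adv_info$db)
    } else {
      grads$disc <- list(W = array(0, dim = dim(p$disc$W)),
                         b = numeric(length(p$disc$b)))
    }
    if (beta != 0) {
      sc <- beta / B
      for (b in seq_len(B)) {
        len <- batch$lens[b]
        dSpre[b, seq_len(len), ] <- dSpre[b, seq_len(len), ] +
          sc * diff_info[[b]]$dS
        dPpre_priv[b, seq_len(len), ] <- dPpre_priv[b, seq_len(len), ] +
          sc * diff_info[[b]]$dP
      }
    }
    dPpre_by_enc$enc_shared <- dSpre
    dPpre_by_enc[[pk]] <- dPpre_priv
  }

  # encoder backward passes; accumulate dX
  dX <- array(0, dim = dim(X))
  for (en in names(encs)) {
    bk <- bilstm_backward(dP_by_enc[[en]] %||%
                            array(0, dim = c(B, TT, proj)),
                          X, batch$mask, p[[en]], encs[[en]]$cache,
                          dP_pre = dPpre_by_enc[[en]])
    grads[[en]] <- bk$grads
    dX <- dX + bk$dX
  }

  ## ---- embedding gradients ----
  dXm <- matrix(dX, B * TT, cfg$d_w + cfg$n_filters)
  dXw <- dXm[, seq_len(cfg$d_w), drop = FALSE]
  dXc <- dXm[, cfg$d_w + seq_len(cfg$n_filters), drop = FALSE]
  demb <- rowsum(dXw, group = w_ids)
  dword <- matrix(0, nrow(p$word_emb), ncol(p$word_emb))
  dword[as.integer(rownames(demb)), ] <- demb
  dword[1, ] <- 0  # PAD
  grads$word_emb <- dword
  grads$cnn <- char_cnn_backward(dXc[batch$real_idx, , drop = FALSE],
                                 p$cnn, cnn_fw$cache)
  out$grads <- grads
  out
}

#' Run one architecture forward over a batch of sentences
#'
#' Convenience wrapper used for prediction and inspection: encodes the
#' sentences with dropout off and returns the CRF emission array plus the
#' component outputs.  Training uses the internal fused
#' forward/backward path.
#'
#' @param model a [build_model()] model.
#' @param sentences list of sentences (`list(tokens=, tags=)`; tags
#'   optional for prediction).
#' @param d dataset index (1 or 2) selecting the CRF head.
#' @param decode if TRUE, Viterbi-decode each sentence.
#' @return list with `emissions` (`(B, T, d_em)` array), `lens`, and when
#'   decoding `tags` (list of character tag vectors).
#' @export
model_forward <- function(model, sentences, d = 1L, decode = TRUE) {
  batch <- make_batch(sentences, model$vocab,
                      names(model$vocab$tag_index)[d], require_tags = FALSE)
  res <- compute_batch(model, batch, d = d, train = FALSE, grad = FALSE,
                       decode = decode)
  out <- list(emissions = res$emissions, lens = batch$lens)
  if (decode) {
    inv <- names(model$vocab$tag_index[[model$datasets[d]]])
    out$tags <- lapply(res$paths, function(pp) inv[pp])
  }
  out
}
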