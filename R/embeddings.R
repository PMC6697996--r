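# Per-token representation x_t = w_t (+) r_t: pretrained/trainable word
# vectors concatenated with a character-level CNN feature vector.

#' Load pretrained word vectors from a text file
#'
#' Auto-detects the two common text dialects: GloVe (no header; every line
#' is `word v1 ... vdim`) and word2vec (first line is `count dim`).  Rows
#' whose field count does not match `dim + 1` are skipped and counted.
#'
#' @param path text file path.
#' @param dim expected vector dimension.
#' @return named list mapping word to numeric vector, with attribute
#'   `skipped` (number of malformed rows).
#' @export
load_pretrained_vectors <- function(path, dim) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no parsable rows in ", path)
  first <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  # word2vec dialect: a 2-field all-numeric header
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first))))
    lines <- lines[-1]
  out <- list(); skipped <- 0L
  for (ln in lines) {
    fields <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(fields) != dim + 1L) { skipped <- skipped + 1L; next }
    v <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(v)) { skipped <- skipped + 1L; next }
    out[[fields[1]]] <- v
  }
  if (!length(out)) stop("no parsable rows in ", path)
  if (skipped > 0)
    message("load_pretrained_vectors: skipped ", skipped, " malformed row(s)")
  attr(out, "skipped") <- skipped
  out
}

#' Construct character-CNN parameters
#'
#' A bank of `n_filters` filters of shape `d_c x l_f` applied to the
#' character-embedding matrix of a word with padding `l_f - 1`, followed by
#' max pooling over the `l_c + l_f - 1` convolution positions.
#'
#' @param n_chars character inventory size (including PAD, UNK).
#' @param d_c character embedding dimension.
#' @param n_filters number of convolution filters (= output dimension).
#' @param l_f filter width.
#' @param seed,name initialization controls.
#' @return list with `char_emb` (PAD row zero), `W` (list of `l_f`
#'   matrices `d_c x n_filters`, one per filter column), and `b`.
#' @export
char_cnn_params <- function(n_chars, d_c = 30L, n_filters = 30L, l_f = 3L,
                            seed = 1L, name = "cnn") {
  emb <- init_param(paste0(name, ".char_emb"), c(n_chars, d_c), seed,
                    range = sqrt(3 / d_c))
  emb[1, ] <- 0  # PAD
  W <- stats::setNames(
    lapply(seq_len(l_f), function(j)
      init_param(paste0(name, ".W", j), c(d_c, n_filters), seed)),
    paste0("w", seq_len(l_f)))
  list(char_emb = emb, W = W, b = init_param(paste0(name, ".b"), n_filters,
                                             seed),
       d_c = d_c, n_filters = n_filters, l_f = l_f)
}

# Pack a list of words (each an integer char-id vector) into the padded
# index matrix the batched CNN consumes.
pack_char_ids <- function(char_id_list, pad_id = 1L) {
  lens <- vapply(char_id_list, length, integer(1))
  L <- max(lens, 1L)
  ids <- matrix(pad_id, length(char_id_list), L)
  for (i in seq_along(char_id_list))
    if (lens[i]) ids[i, seq_len(lens[i])] <- char_id_list[[i]]
  list(ids = ids, lens = lens)
}

#' Character-CNN encoding of a batch of words
#'
#' Convolution with padding `l_f - 1` yields `l_c + l_f - 1` positions per
#' filter; positions whose window lies beyond a word's last character are
#' masked to `-Inf` before the max, so the output is invariant to trailing
#' padding.  Returns the pooled `n_words x n_filters` matrix plus the cache
#' needed for the backward pass.
#'
#' @param ids integer matrix `n_words x L` of char indices (PAD = 1).
#' @param lens integer vector of true word lengths (all >= 1).
#' @param params from [char_cnn_params()].
#' @param drop_mask optional dropout mask over the char embeddings (the
#'   CNN-input dropout), same shape as the embedded matrix.
#' @return list(`r` = pooled output, `cache`).
#' @export
char_cnn_forward <- function(ids, lens, params, drop_mask = NULL) {
  if (any(lens < 1L)) stop("empty word: pad upstream")
  nw <- nrow(ids); L <- ncol(ids); lf <- params$l_f
  P <- L + lf - 1L                      # pooled-over positions
  Lp <- L + 2L * (lf - 1L)              # padded width
  pad_ids <- cbind(matrix(1L, nw, lf - 1L), ids, matrix(1L, nw, lf - 1L))
  # embedded chars, row-major by (word, padded position)
  flat_ids <- as.integer(t(pad_ids))    # word-major, position fastest
  E <- params$char_emb[flat_ids, , drop = FALSE]  # (nw*Lp) x d_c
  E <- apply_mask(E, drop_mask)
  # response[(word,pos), filter] = sum_j E[word, pos+j-1, ] %*% W[[j]] + b
  base <- rep((seq_len(nw) - 1L) * Lp, each = P) + seq_len(P)  # pos s in padded coords
  resp <- matrix(rep(params$b, each = nw * P), nw * P, params$n_filters)
  idxs <- vector("list", lf)
  for (j in seq_len(lf)) {
    idxs[[j]] <- base + (j - 1L)
    resp <- resp + E[idxs[[j]], , drop = FALSE] %*% params$W[[j]]
  }
  # mask positions beyond l_c + l_f - 1 for each word
  pos <- rep(seq_len(P), times = nw)
  valid <- pos <= rep(lens, each = P) + lf - 1L
  respm <- resp
  respm[!valid, ] <- -Inf
  # max-pool per word per filter; first max = deterministic argmax
  M <- matrix(respm, nrow = P)                 # P x (nw*n_filters)
  amax <- max.col(t(M), ties.method = "first") # length nw*n_filters
  pooled_vals <- M[cbind(amax, seq_along(amax))]
  r <- matrix(pooled_vals, nw, params$n_filters)
  list(r = r,
       cache = list(E = E, idxs = idxs, amax = amax, nw = nw, P = P,
                    Lp = Lp, flat_ids = flat_ids, drop_mask = drop_mask))
}

#' Backward pass of the character CNN
#'
#' @param dr gradient of the loss w.r.t. the pooled output
#'   (`n_words x n_filters`).
#' @param params,cache from [char_cnn_forward()].
#' @return list of gradients: `char_emb`, `W` (list), `b`.
#' @export
char_cnn_backward <- function(dr, params, cache) {
  nw <- cache$nw; P <- cache$P; lf <- params$l_f; nf <- params$n_filters
  # route pooled gradient to winning positions
  dresp <- matrix(0, nw * P, nf)
  word_of <- rep(seq_len(nw), times = nf)     # column-major over (word, filter)
  filt_of <- rep(seq_len(nf), each = nw)
  rows <- (word_of - 1L) * P + cache$amax
  dresp[cbind(rows, filt_of)] <- as.vector(dr)
  dW <- vector("list", lf)
  dE <- matrix(0, nrow(cache$E), ncol(cache$E))
  for (j in seq_len(lf)) {
    Ej <- cache$E[cache$idxs[[j]], , drop = FALSE]
    dW[[j]] <- t(Ej) %*% dresp
    dE[cache$idxs[[j]], ] <- dE[cache$idxs[[j]], , drop = FALSE] +
      dresp %*% t(params$W[[j]])
  }
  names(dW) <- names(params$W)
  db <- colSums(dresp)
  dE <- apply_mask(dE, cache$drop_mask)
  demb <- rowsum(dE, group = cache$flat_ids)
  dchar_emb <- matrix(0, nrow(params$char_emb), ncol(params$char_emb))
  gidx <- as.integer(rownames(demb))
  dchar_emb[gidx, ] <- demb
  dchar_emb[1, ] <- 0  # PAD embedding is fixed at zero
  list(char_emb = dchar_emb, W = dW, b = db)
}

#' Concatenate word vector and character representation
#'
#' Word part first, character part second; slicing the result at the word
#' dimension recovers both inputs exactly.
#'
#' @param w matrix of word vectors (rows = tokens).
#' @param r matrix of char-CNN outputs (rows = tokens).
#' @return matrix `x` with `ncol(w) + ncol(r)` columns.
#' @export
compose_word_representation <- function(w, r) {
  w <- as.matrix(w); r <- as.matrix(r)
  if (nrow(w) != nrow(r)) stop("configuration error: row mismatch")
  cbind(w, r)
}
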