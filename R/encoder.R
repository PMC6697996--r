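# LSTM cell, bidirectional encoder and the output projection shared by all
# architectures.  Forward passes keep the caches required for analytic
# backpropagation through time; padded positions carry the previous state
# through unchanged and contribute nothing to gradients.

#' Construct the parameters of one LSTM direction
#'
#' Gate weights act on the concatenation `[h_prev, x_t]` (hidden part
#' first).  The forget-gate bias is initialized to 1 so early training does
#' not erase the cell state; all other entries are uniform in
#' `[-0.1, 0.1]`.
#'
#' @param input input dimension.
#' @param hidden hidden state dimension.
#' @param seed,name initialization controls.
#' @return list with `W_f`, `W_i`, `W_C`, `W_o` (each
#'   `hidden x (hidden + input)`), biases `b_f` (= 1), `b_i`, `b_C`, `b_o`,
#'   and `hidden`.
#' @export
lstm_params <- function(input, hidden, seed = 1L, name = "lstm") {
  mk <- function(suffix) init_param(paste0(name, ".", suffix),
                                    c(hidden, hidden + input), seed)
  mkb <- function(suffix) init_param(paste0(name, ".", suffix), hidden, seed)
  list(W_f = mk("W_f"), W_i = mk("W_i"), W_C = mk("W_C"), W_o = mk("W_o"),
       b_f = mkb("b_f") + 1, b_i = mkb("b_i"), b_C = mkb("b_C"),
       b_o = mkb("b_o"), hidden = hidden)
}

#' One LSTM cell step
#'
#' Implements the standard gate equations
#' `f_t = sigma(W_f [h_prev, x_t] + b_f)`, likewise for `i_t` and `o_t`,
#' `C~_t = tanh(W_C [h_prev, x_t] + b_C)`,
#' `C_t = f_t * C_{t-1} + i_t * C~_t`, `h_t = o_t * tanh(C_t)`.
#'
#' @param x_t input vector (or `B x input` matrix for a batch).
#' @param h_prev,C_prev previous hidden and cell state (vector or matrix
#'   conformable with `x_t`).
#' @param params from [lstm_params()].
#' @return list with `h`, `C` (and `cache` when `keep_cache = TRUE`).
#' @param keep_cache retain intermediates for backpropagation.
#' @export
lstm_cell_step <- function(x_t, h_prev, C_prev, params, keep_cache = FALSE) {
  x_t <- rbind(x_t); h_prev <- rbind(h_prev); C_prev <- rbind(C_prev)
  dimnames(x_t) <- dimnames(h_prev) <- dimnames(C_prev) <- NULL
  if (ncol(h_prev) != params$hidden ||
      ncol(x_t) + ncol(h_prev) != ncol(params$W_f))
    stop("configuration error: dimension mismatch in LSTM step")
  HX <- cbind(h_prev, x_t)
  f <- sigmoid(HX %*% t(params$W_f) + rep(params$b_f, each = nrow(HX)))
  i <- sigmoid(HX %*% t(params$W_i) + rep(params$b_i, each = nrow(HX)))
  Ctil <- tanh(HX %*% t(params$W_C) + rep(params$b_C, each = nrow(HX)))
  o <- sigmoid(HX %*% t(params$W_o) + rep(params$b_o, each = nrow(HX)))
  C <- f * C_prev + i * Ctil
  h <- o * tanh(C)
  out <- list(h = h, C = C)
  if (keep_cache)
    out$cache <- list(HX = HX, f = f, i = i, Ctil = Ctil, o = o, C = C,
                      C_prev = C_prev)
  out
}

# Batched unidirectional LSTM over a (B, T, d) input array.
# mask: B x T matrix, 1 for real tokens, 0 for padding; padded steps carry
# h and C through unchanged.
lstm_forward <- function(X, mask, params) {
  B <- dim(X)[1]; TT <- dim(X)[2]
  hd <- params$hidden
  h <- matrix(0, B, hd); C <- matrix(0, B, hd)
  H <- array(0, dim = c(B, TT, hd))
  caches <- vector("list", TT)
  for (t in seq_len(TT)) {
    x_t <- matrix(X[, t, ], B)
    st <- lstm_cell_step(x_t, h, C, params, keep_cache = TRUE)
    m <- mask[, t]
    h_new <- st$h * m + h * (1 - m)
    C_new <- st$C * m + C * (1 - m)
    caches[[t]] <- c(st$cache, list(m = m, h_prev = h))
    h <- h_new; C <- C_new
    H[, t, ] <- h
  }
  list(H = H, caches = caches)
}

# Backward pass of lstm_forward.  dH: (B, T, hidden) gradients flowing into
# each (post-mask) h_t from outside.  Returns dX and parameter gradients.
lstm_backward <- function(dH, X, params, caches) {
  B <- dim(dH)[1]; TT <- dim(dH)[2]; hd <- params$hidden
  din <- dim(X)[3]
  dX <- array(0, dim = dim(X))
  g <- list(W_f = matrix(0, hd, hd + din), W_i = matrix(0, hd, hd + din),
            W_C = matrix(0, hd, hd + din), W_o = matrix(0, hd, hd + din),
            b_f = numeric(hd), b_i = numeric(hd), b_C = numeric(hd),
            b_o = numeric(hd))
  dh_carry <- matrix(0, B, hd); dC_carry <- matrix(0, B, hd)
  for (t in rev(seq_len(TT))) {
    ca <- caches[[t]]
    m <- ca$m
    dh_tot <- matrix(dH[, t, ], B) + dh_carry
    # through the mask carry: h_t = m*h_new + (1-m)*h_prev
    dh_new <- dh_tot * m
    dh_prev_carry <- dh_tot * (1 - m)
    dC_new <- dC_carry * m
    dC_prev_carry <- dC_carry * (1 - m)
    # h_new = o * tanh(C_new)
    tC <- tanh(ca$C)
    do_ <- dh_new * tC
    dC_new <- dC_new + dh_new * ca$o * (1 - tC^2)
    # C_new = f*C_prev + i*Ctil
    df <- dC_new * ca$C_prev
    di <- dC_new * ca$Ctil
    dCtil <- dC_new * ca$i
    dC_prev <- dC_new * ca$f
    # pre-activation gradients
    draw_f <- df * ca$f * (1 - ca$f)
    draw_i <- di * ca$i * (1 - ca$i)
    draw_C <- dCtil * (1 - ca$Ctil^2)
    draw_o <- do_ * ca$o * (1 - ca$o)
    HX <- ca$HX
    g$W_f <- g$W_f + t(draw_f) %*% HX
    g$W_i <- g$W_i + t(draw_i) %*% HX
    g$W_C <- g$W_C + t(draw_C) %*% HX
    g$W_o <- g$W_o + t(draw_o) %*% HX
    g$b_f <- g$b_f + colSums(draw_f)
    g$b_i <- g$b_i + colSums(draw_i)
    g$b_C <- g$b_C + colSums(draw_C)
    g$b_o <- g$b_o + colSums(draw_o)
    dHX <- draw_f %*% params$W_f + draw_i %*% params$W_i +
      draw_C %*% params$W_C + draw_o %*% params$W_o
    dh_prev <- dHX[, seq_len(hd), drop = FALSE]
    dX[, t, ] <- dHX[, hd + seq_len(din), drop = FALSE]
    dh_carry <- dh_prev + dh_prev_carry
    dC_carry <- dC_prev + dC_prev_carry
  }
  list(dX = dX, grads = g)
}

#' Construct bidirectional-encoder parameters
#'
#' One forward and one backward LSTM of equal hidden size plus an affine
#' projection mapping the concatenated `2 * hidden` output to `proj`
#' dimensions (a linear unit, no nonlinearity).
#'
#' @param input input dimension.
#' @param hidden per-direction hidden size.
#' @param proj projected output dimension.
#' @param seed,name initialization controls.
#' @return list with `fwd`, `bwd` ([lstm_params()]), `W_p`
#'   (`proj x 2 hidden`), `b_p`, and the dimensions.
#' @export
bilstm_params <- function(input, hidden, proj, seed = 1L, name = "enc") {
  list(fwd = lstm_params(input, hidden, seed, paste0(name, ".f")),
       bwd = lstm_params(input, hidden, seed, paste0(name, ".b")),
       W_p = init_param(paste0(name, ".proj.W"), c(proj, 2L * hidden), seed),
       b_p = init_param(paste0(name, ".proj.b"), proj, seed),
       hidden = hidden, proj = proj)
}

#' Project a concatenated bidirectional output to the encoder dimension
#'
#' @param o vector (or matrix of row vectors) of dimension `2 * hidden`.
#' @param params from [bilstm_params()].
#' @return projected vector(s) of dimension `proj`.
#' @export
project_hidden <- function(o, params) {
  o <- rbind(o)
  if (ncol(o) != ncol(params$W_p)) stop("configuration error: projection input dim")
  o %*% t(params$W_p) + rep(params$b_p, each = nrow(o))
}

#' Bidirectional LSTM encoding of a padded batch
#'
#' Runs the forward LSTM left-to-right and the backward LSTM over the
#' reversed sequence, concatenates per position (forward half first) and
#' applies the output projection.  Dropout, when active, is applied to the
#' input array and to the projected output with inverted scaling.
#'
#' @param X input array `(B, T, input)`.
#' @param mask `B x T` matrix (1 = real token).
#' @param params from [bilstm_params()].
#' @param dropout dropout rate for the input/output dropout layers.
#' @param train logical; dropout is active only during training.
#' @return list with `P` (`(B, T, proj)` projected outputs after output
#'   dropout), `P_pre` (before output dropout; the discriminator and the
#'   orthogonality loss read this), and `cache`.
#' @export
bilstm_encode <- function(X, mask, params, dropout = 0, train = FALSE) {
  B <- dim(X)[1]; TT <- dim(X)[2]
  if (TT < 1L) stop("empty sequence")
  m_in <- dropout_mask(dim(X), dropout, train)
  Xd <- apply_mask(X, m_in)
  fw <- lstm_forward(Xd, mask, params$fwd)
  Xr <- Xd[, rev(seq_len(TT)), , drop = FALSE]
  maskr <- mask[, rev(seq_len(TT)), drop = FALSE]
  bw <- lstm_forward(Xr, maskr, params$bwd)
  hd <- params$hidden
  O <- array(0, dim = c(B, TT, 2L * hd))
  O[, , seq_len(hd)] <- fw$H
  O[, , hd + seq_len(hd)] <- bw$H[, rev(seq_len(TT)), , drop = FALSE]
  Om <- matrix(O, B * TT, 2L * hd)   # (b,t) pairs, b fastest
  Pm <- Om %*% t(params$W_p) + rep(params$b_p, each = B * TT)
  P_pre <- array(Pm, dim = c(B, TT, params$proj))
  m_out <- dropout_mask(dim(P_pre), dropout, train)
  P <- apply_mask(P_pre, m_out)
  list(P = P, P_pre = P_pre,
       cache = list(fw = fw, bw = bw, Om = Om, m_in = m_in, m_out = m_out,
                    Xd = Xd, Xr = Xr, maskr = maskr))
}

#' Backward pass of [bilstm_encode()]
#'
#' @param dP gradient w.r.t. the post-dropout output `P`.
#' @param dP_pre optional extra gradient w.r.t. `P_pre` (paths that read
#'   the pre-dropout projection, e.g. the discriminator).
#' @param X,mask,params,cache as in the forward call.
#' @return list with `dX` (gradient w.r.t. the input array) and `grads`
#'   (named `fwd`, `bwd`, `W_p`, `b_p`).
#' @export
bilstm_backward <- function(dP, X, mask, params, cache, dP_pre = NULL) {
  B <- dim(X)[1]; TT <- dim(X)[2]; hd <- params$hidden
  dPp <- apply_mask(dP, cache$m_out)
  if (!is.null(dP_pre)) dPp <- dPp + dP_pre
  dPm <- matrix(dPp, B * TT, params$proj)
  dW_p <- t(dPm) %*% cache$Om
  db_p <- colSums(dPm)
  dOm <- dPm %*% params$W_p
  dO <- array(dOm, dim = c(B, TT, 2L * hd))
  dHf <- dO[, , seq_len(hd), drop = FALSE]
  dHb_fwdorder <- dO[, , hd + seq_len(hd), drop = FALSE]
  dHb <- dHb_fwdorder[, rev(seq_len(TT)), , drop = FALSE]
  bf <- lstm_backward(dHf, cache$Xd, params$fwd, cache$fw$caches)
  bb <- lstm_backward(dHb, cache$Xr, params$bwd, cache$bw$caches)
  dXd <- bf$dX + bb$dX[, rev(seq_len(TT)), , drop = FALSE]
  dX <- apply_mask(dXd, cache$m_in)
  list(dX = dX,
       grads = list(fwd = bf$grads, bwd = bb$grads, W_p = dW_p, b_p = db_p))
}
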