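# Dynamic Hyperbolic Token Statistics Transformer (DHTST).
#
# Replaces the similarity-attention stage at the end of the backbone. A 1x1
# conv splits channels 1:1 into a main and an auxiliary branch. The auxiliary
# branch is dynamised by a learnable tanh layer (DyT), flattened to tokens,
# passed through token-statistics attention (weights from second-order token
# statistics instead of query-key similarity), and residually rejoined; the
# concatenated features pass a second DyT and a two-layer 1x1 FFN with a
# residual connection.

#' Construct a dynamic-tanh (DyT) layer
#'
#' Computes `beta * tanh(alpha * x + gamma)` elementwise with learnable
#' per-channel scaling `alpha`, weight `beta` and bias compensation `gamma`.
#' Output magnitude is bounded by `|beta|`.
#'
#' @param channels channel count.
#' @param alpha0 initial value of `alpha` (default 0.5).
#' @return a DyT module.
#' @export
dyt_layer <- function(channels, alpha0 = 0.5) {
  new_module("m_dyt",
             params = list(alpha = tensor(rep(alpha0, channels), TRUE),
                           beta = tensor(rep(1, channels), TRUE),
                           gamma = tensor(numeric(channels), TRUE)),
             channels = channels)
}

mod_forward.m_dyt <- function(m, x, ...) {
  op_cscale(op_tanh(op_cshift(op_cscale(x, m$params$alpha), m$params$gamma)),
            m$params$beta)
}

mod_trace.m_dyt <- function(m, shape) list(shape = shape, macs = 0)

#' Apply a DyT layer to an array
#'
#' @param block module from [dyt_layer()].
#' @param x numeric (H, W, C) array or (n, C) token matrix.
#' @return same shape as `x`.
#' @export
dyt <- function(block, x) {
  stopifnot(inherits(block, "m_dyt"))
  with_no_grad(mod_forward(block, tensor(x)))$v
}

# ---- token-statistics attention --------------------------------------------

#' Construct a token-statistics attention layer
#'
#' Tokens are linearly projected and split into heads; per-head attention
#' weights are a softmax over the temperature-scaled squared norms of the
#' projected tokens (second-order token statistics -- no n x n similarity
#' matrix is formed). The projected tokens are rescaled by the weights and by
#' an epsilon-stabilised inverse square root of the weighted second moment,
#' gated per head, merged, and linearly projected back.
#'
#' @param dim token feature dimension (must be divisible by `heads`).
#' @param heads number of attention heads.
#' @param eps numerical floor of the second-moment normalisation.
#' @param dropout dropout rate on the attention weights (0 disables; kept at 0
#'   for deterministic inference).
#' @return a token-attention module.
#' @export
token_attention <- function(dim, heads = 4L, eps = 1e-6, dropout = 0) {
  if (dim %% heads != 0L)
    stop("token dimension not divisible by head count", call. = FALSE)
  new_module("m_tsattn",
             params = list(
               w1 = tensor(matrix(init_w(dim * dim, dim), dim, dim), TRUE),
               b1 = tensor(numeric(dim), TRUE),
               tau = tensor(rep(1, heads), TRUE),
               lam = tensor(rep(1, heads), TRUE),
               w2 = tensor(matrix(init_w(dim * dim, dim), dim, dim), TRUE),
               b2 = tensor(numeric(dim), TRUE)),
             dim = dim, heads = heads, d = dim %/% heads, eps = eps,
             dropout = dropout)
}

# vector * scalar-tensor and matrix * scalar-tensor helpers
op_vscale <- function(a, s) {
  tns_op(a$v * s$v, list(a, s), function(g) list(g * s$v, sum(g * a$v)))
}

mod_forward.m_tsattn <- function(m, x, ...) {
  if (nrow(x$v) < 1L) stop("attention needs at least one token", call. = FALSE)
  p <- op_addrow(op_matmul(x, m$params$w1), m$params$b1)
  outs <- vector("list", m$heads)
  for (h in seq_len(m$heads)) {
    cols <- (h - 1L) * m$d + seq_len(m$d)
    ph <- op_slice_cols(p, cols[1], cols[m$d])
    sq <- op_square(ph)
    scores <- op_vscale(op_rowsum(sq), op_index(m$params$tau, h))
    pi_h <- op_softmax(scores)                       # sums to 1 over tokens
    if (m$dropout > 0) {
      keep <- stats::rbinom(length(pi_h$v), 1, 1 - m$dropout) / (1 - m$dropout)
      pi_h <- op_mul(pi_h, tensor(keep))
    }
    m2 <- op_colsum(op_rowscale(sq, pi_h))           # weighted second moment
    rescale <- op_recip(op_sqrt_eps(m2, m$eps))
    fh <- op_colscale(op_rowscale(ph, pi_h), rescale)
    outs[[h]] <- op_mscale(fh, op_index(m$params$lam, h))
  }
  op_addrow(op_matmul(cbind_cols(outs), m$params$w2), m$params$b2)
}

op_mscale <- function(a, s) {  # matrix * scalar tensor
  tns_op(a$v * s$v, list(a, s), function(g) list(g * s$v, sum(g * a$v)))
}

mod_trace.m_tsattn <- function(m, shape) {
  # shape = c(n, dim); two dense projections dominate
  list(shape = shape, macs = 2 * shape[1] * as.numeric(m$dim)^2)
}

#' Token-statistics attention on a token matrix
#'
#' @param block module from [token_attention()].
#' @param x numeric (n, dim) token matrix.
#' @return numeric (n, dim) matrix.
#' @export
token_stat_attention <- function(block, x) {
  stopifnot(inherits(block, "m_tsattn"))
  if (NROW(x) < 1L) stop("attention needs at least one token", call. = FALSE)
  with_no_grad(mod_forward(block, tensor(x)))$v
}

#' Per-head token-statistics attention weights
#'
#' Returns the softmax weights `Pi` (heads x n); each row sums to 1.
#'
#' @inheritParams token_stat_attention
#' @export
token_attention_weights <- function(block, x) {
  stopifnot(inherits(block, "m_tsattn"))
  p <- sweep(x %*% block$params$w1$v, 2, block$params$b1$v, "+")
  out <- matrix(0, block$heads, nrow(p))
  for (h in seq_len(block$heads)) {
    cols <- (h - 1L) * block$d + seq_len(block$d)
    s <- rowSums(p[, cols, drop = FALSE]^2) * block$params$tau$v[h]
    e <- exp(s - max(s))
    out[h, ] <- e / sum(e)
  }
  out
}

# ---- full block ------------------------------------------------------------

#' Construct a DHTST block
#'
#' @param channels block width (even); the 1:1 split sends half through the
#'   dynamised attention branch.
#' @param heads attention heads.
#' @param eps second-moment stabiliser.
#' @param dropout attention dropout rate (0 = deterministic).
#' @return a DHTST module usable with [dhtst_forward()].
#' @export
dhtst <- function(channels, heads = 4L, eps = 1e-6, dropout = 0) {
  if (channels %% 2L != 0L) stop("channel count must be even", call. = FALSE)
  ch <- channels %/% 2L
  new_module("m_dhtst",
             children = list(
               cv1 = m_conv(channels, channels, 1L),
               dyt1 = dyt_layer(ch),
               attn = token_attention(ch, heads, eps, dropout),
               dyt2 = dyt_layer(channels),
               ffn1 = m_conv(channels, channels, 1L),
               ffn2 = m_conv(channels, channels, 1L, act = "none")),
             nchan = channels, nhalf = ch)
}

mod_forward.m_dhtst <- function(m, x, ...) {
  d <- dim(x$v)
  y <- mod_forward(m$children$cv1, x)
  main <- op_slice_c(y, 1L, m$nhalf)
  aux <- op_slice_c(y, m$nhalf + 1L, m$nchan)
  a <- mod_forward(m$children$dyt1, aux)
  att <- mod_forward(m$children$attn, op_tokens(a))
  aux_out <- op_add(aux, op_untokens(att, d[1], d[2]))
  f1 <- op_concat_c(list(main, aux_out))
  y2 <- mod_forward(m$children$ffn2,
                    mod_forward(m$children$ffn1, mod_forward(m$children$dyt2, f1)))
  op_add(f1, y2)
}

mod_trace.m_dhtst <- function(m, shape) {
  n <- shape[1] * shape[2]
  macs <- mod_trace(m$children$cv1, shape)$macs +
    mod_trace(m$children$attn, c(n, m$nhalf))$macs +
    mod_trace(m$children$ffn1, shape)$macs + mod_trace(m$children$ffn2, shape)$macs
  list(shape = shape, macs = macs)
}

#' Forward pass through a DHTST block
#'
#' @param block module from [dhtst()].
#' @param x numeric (H, W, channels) array.
#' @return array of the same shape.
#' @export
dhtst_forward <- function(block, x) {
  stopifnot(inherits(block, "m_dhtst"))
  with_no_grad(mod_forward(block, tensor(x)))$v
}
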