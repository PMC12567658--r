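# Reference nano-detector blocks: CSP bottlenecks (C3k2 family), SPPF, the
# position-sensitive attention stage (C2PSA), and the decoupled detect head.
# These reconstruct the publicly documented nano layout that the improved
# model is measured against.

m_bottleneck <- function(c1, c2, shortcut = TRUE, k = 3L, e = 0.5) {
  c_ <- as.integer(c2 * e)
  new_module("m_bottleneck",
             children = list(cv1 = m_conv(c1, c_, k), cv2 = m_conv(c_, c2, k)),
             add = shortcut && c1 == c2)
}

mod_forward.m_bottleneck <- function(m, x, ...) {
  y <- mod_forward(m$children$cv2, mod_forward(m$children$cv1, x))
  if (m$add) op_add(x, y) else y
}

mod_trace.m_bottleneck <- function(m, shape) {
  t1 <- mod_trace(m$children$cv1, shape)
  t2 <- mod_trace(m$children$cv2, t1$shape)
  list(shape = t2$shape, macs = t1$macs + t2$macs)
}

m_c3k <- function(c1, c2, n = 2L, e = 0.5) {
  c_ <- as.integer(c2 * e)
  btl <- lapply(seq_len(n), function(i) m_bottleneck(c_, c_, TRUE, 3L, 1.0))
  names(btl) <- paste0("m", seq_len(n))
  new_module("m_c3k",
             children = c(list(cv1 = m_conv(c1, c_, 1L), cv2 = m_conv(c1, c_, 1L),
                               cv3 = m_conv(2L * c_, c2, 1L)), btl),
             n = n)
}

mod_forward.m_c3k <- function(m, x, ...) {
  a <- mod_forward(m$children$cv1, x)
  for (i in seq_len(m$n)) a <- mod_forward(m$children[[paste0("m", i)]], a)
  b <- mod_forward(m$children$cv2, x)
  mod_forward(m$children$cv3, op_concat_c(list(a, b)))
}

mod_trace.m_c3k <- function(m, shape) {
  t1 <- mod_trace(m$children$cv1, shape)
  macs <- t1$macs
  s <- t1$shape
  for (i in seq_len(m$n)) {
    tb <- mod_trace(m$children[[paste0("m", i)]], s)
    macs <- macs + tb$macs
    s <- tb$shape
  }
  t2 <- mod_trace(m$children$cv2, shape)
  t3 <- mod_trace(m$children$cv3, c(s[1], s[2], s[3] + t2$shape[3]))
  list(shape = t3$shape, macs = macs + t2$macs + t3$macs)
}

# CSP block with a 1x1 split conv, n inner units on the last split half, and a
# 1x1 merge over all partial features.
m_c3k2 <- function(c1, c2, n = 1L, c3k = FALSE, e = 0.5, shortcut = TRUE) {
  c <- as.integer(c2 * e)
  units <- lapply(seq_len(n), function(i) {
    if (c3k) m_c3k(c, c, 2L) else m_bottleneck(c, c, shortcut, 3L, 0.5)
  })
  names(units) <- paste0("m", seq_len(n))
  new_module("m_c3k2",
             children = c(list(cv1 = m_conv(c1, 2L * c, 1L),
                               cv2 = m_conv((2L + n) * c, c2, 1L)), units),
             cmid = c, n = n)
}

mod_forward.m_c3k2 <- function(m, x, ...) {
  y <- mod_forward(m$children$cv1, x)
  parts <- list(op_slice_c(y, 1L, m$cmid), op_slice_c(y, m$cmid + 1L, 2L * m$cmid))
  for (i in seq_len(m$n)) {
    parts[[2L + i]] <- mod_forward(m$children[[paste0("m", i)]], parts[[length(parts)]])
  }
  mod_forward(m$children$cv2, op_concat_c(parts))
}

mod_trace.m_c3k2 <- function(m, shape) {
  t1 <- mod_trace(m$children$cv1, shape)
  macs <- t1$macs
  s <- c(t1$shape[1], t1$shape[2], m$cmid)
  for (i in seq_len(m$n)) {
    tu <- mod_trace(m$children[[paste0("m", i)]], s)
    macs <- macs + tu$macs
    s <- tu$shape
  }
  t2 <- mod_trace(m$children$cv2, c(s[1], s[2], (2L + m$n) * m$cmid))
  list(shape = t2$shape, macs = macs + t2$macs)
}

m_sppf <- function(c1, c2, k = 5L) {
  c_ <- c1 %/% 2L
  new_module("m_sppf",
             children = list(cv1 = m_conv(c1, c_, 1L), cv2 = m_conv(4L * c_, c2, 1L)),
             k = k)
}

mod_forward.m_sppf <- function(m, x, ...) {
  y <- mod_forward(m$children$cv1, x)
  p1 <- op_maxpool(y, m$k, 1L, m$k %/% 2L)
  p2 <- op_maxpool(p1, m$k, 1L, m$k %/% 2L)
  p3 <- op_maxpool(p2, m$k, 1L, m$k %/% 2L)
  mod_forward(m$children$cv2, op_concat_c(list(y, p1, p2, p3)))
}

mod_trace.m_sppf <- function(m, shape) {
  t1 <- mod_trace(m$children$cv1, shape)
  t2 <- mod_trace(m$children$cv2, c(t1$shape[1], t1$shape[2], 4L * t1$shape[3]))
  list(shape = t2$shape, macs = t1$macs + t2$macs)
}

# ---- similarity attention stage of the reference model ---------------------

m_attention <- function(dim, num_heads, attn_ratio = 0.5) {
  head_dim <- dim %/% num_heads
  key_dim <- as.integer(head_dim * attn_ratio)
  h <- dim + key_dim * num_heads * 2L
  new_module("m_attention",
             children = list(qkv = m_conv(dim, h, 1L, act = "none"),
                             proj = m_conv(dim, dim, 1L, act = "none"),
                             pe = m_conv(dim, dim, 3L, groups = dim, act = "none")),
             dim = dim, heads = num_heads, key_dim = key_dim, head_dim = head_dim,
             scale = key_dim^-0.5)
}

mod_forward.m_attention <- function(m, x, ...) {
  d <- dim(x$v)
  qkv <- mod_forward(m$children$qkv, x)
  tok <- op_tokens(qkv)  # n x (2*kd*h + dim)
  outs <- vector("list", m$heads)
  per <- 2L * m$key_dim + m$head_dim
  for (hh in seq_len(m$heads)) {
    base <- (hh - 1L) * per
    q <- op_slice_cols(tok, base + 1L, base + m$key_dim)
    k <- op_slice_cols(tok, base + m$key_dim + 1L, base + 2L * m$key_dim)
    v <- op_slice_cols(tok, base + 2L * m$key_dim + 1L, base + per)
    att <- op_smul(op_matmul(q, t_of(k)), m$scale)  # n x n
    att <- softmax_rows(att)
    outs[[hh]] <- op_matmul(att, v)
  }
  merged <- do.call(cbind_cols, list(outs))
  vmap <- op_untokens(merged, d[1], d[2])
  vpe <- mod_forward(m$children$pe, vmap)
  mod_forward(m$children$proj, op_add(vmap, vpe))
}

mod_trace.m_attention <- function(m, shape) {
  n <- shape[1] * shape[2]
  macs <- mod_trace(m$children$qkv, shape)$macs +
    mod_trace(m$children$pe, shape)$macs +
    mod_trace(m$children$proj, shape)$macs +
    m$heads * (n * n * m$key_dim + n * n * m$head_dim)
  list(shape = c(shape[1], shape[2], m$dim), macs = macs)
}

m_psablock <- function(c) {
  new_module("m_psablock",
             children = list(
               attn = m_attention(c, num_heads = c %/% 64L, attn_ratio = 0.5),
               ffn1 = m_conv(c, 2L * c, 1L), ffn2 = m_conv(2L * c, c, 1L, act = "none")))
}

mod_forward.m_psablock <- function(m, x, ...) {
  x <- op_add(x, mod_forward(m$children$attn, x))
  op_add(x, mod_forward(m$children$ffn2, mod_forward(m$children$ffn1, x)))
}

mod_trace.m_psablock <- function(m, shape) {
  macs <- mod_trace(m$children$attn, shape)$macs +
    mod_trace(m$children$ffn1, shape)$macs + mod_trace(m$children$ffn2, shape)$macs
  list(shape = shape, macs = macs)
}

m_c2psa <- function(c, n = 1L) {
  ch <- c %/% 2L
  blocks <- lapply(seq_len(n), function(i) m_psablock(ch))
  names(blocks) <- paste0("m", seq_len(n))
  new_module("m_c2psa",
             children = c(list(cv1 = m_conv(c, c, 1L), cv2 = m_conv(c, c, 1L)), blocks),
             cmid = ch, n = n)
}

mod_forward.m_c2psa <- function(m, x, ...) {
  y <- mod_forward(m$children$cv1, x)
  a <- op_slice_c(y, 1L, m$cmid)
  b <- op_slice_c(y, m$cmid + 1L, 2L * m$cmid)
  for (i in seq_len(m$n)) b <- mod_forward(m$children[[paste0("m", i)]], b)
  mod_forward(m$children$cv2, op_concat_c(list(a, b)))
}

mod_trace.m_c2psa <- function(m, shape) {
  macs <- mod_trace(m$children$cv1, shape)$macs + mod_trace(m$children$cv2, shape)$macs
  s <- c(shape[1], shape[2], m$cmid)
  for (i in seq_len(m$n)) macs <- macs + mod_trace(m$children[[paste0("m", i)]], s)$macs
  list(shape = shape, macs = macs)
}

# matrix transpose / cbind as tape ops (used only by the reference attention)
t_of <- function(a) tns_op(t(a$v), list(a), function(g) list(t(g)))

cbind_cols <- function(xs) {
  vs <- lapply(xs, function(x) x$v)
  ks <- vapply(vs, ncol, numeric(1))
  tns_op(do.call(cbind, vs), xs, function(g) {
    res <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      res[[i]] <- g[, at + seq_len(ks[i]), drop = FALSE]
      at <- at + ks[i]
    }
    res
  })
}

softmax_rows <- function(a) {
  z <- a$v - apply(a$v, 1, max)
  e <- exp(z)
  s <- e / rowSums(e)
  tns_op(s, list(a), function(g) list(s * (g - rowSums(g * s))))
}

# ---- decoupled detect head (distribution-focal box branch + class branch) --

m_detect <- function(chs, nc = 1L, reg_max = 16L) {
  c2 <- max(16L, chs[1] %/% 4L, reg_max * 4L)
  c3 <- max(chs[1], min(nc, 100L))
  lv <- function(i) {
    x <- chs[i]
    list(
      box = m_seq(m_conv(x, c2, 3L), m_conv(c2, c2, 3L),
                  m_conv(c2, 4L * reg_max, 1L, act = "none")),
      cls = m_seq(m_conv(x, x, 3L, groups = x), m_conv(x, c3, 1L),
                  m_conv(c3, c3, 3L, groups = c3), m_conv(c3, c3, 1L),
                  m_conv(c3, nc, 1L, act = "none")))
  }
  levels <- lapply(seq_along(chs), lv)
  ch <- list()
  for (i in seq_along(levels)) {
    ch[[paste0("box", i)]] <- levels[[i]]$box
    ch[[paste0("cls", i)]] <- levels[[i]]$cls
  }
  new_module("m_detect", children = ch, chs = chs, nc = nc, reg_max = reg_max)
}

# input: list of pyramid maps; output: per level list(box=, cls=) raw maps
mod_forward.m_detect <- function(m, x, ...) {
  lapply(seq_along(x), function(i) {
    list(box = mod_forward(m$children[[paste0("box", i)]], x[[i]]),
         cls = mod_forward(m$children[[paste0("cls", i)]], x[[i]]))
  })
}

mod_trace.m_detect <- function(m, shape) {
  # `shape` is a list of level shapes for the head
  macs <- 0
  for (i in seq_along(shape)) {
    macs <- macs + mod_trace(m$children[[paste0("box", i)]], shape[[i]])$macs +
      mod_trace(m$children[[paste0("cls", i)]], shape[[i]])$macs
  }
  list(shape = shape, macs = macs)
}
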