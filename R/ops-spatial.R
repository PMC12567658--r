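# Spatial primitives on (H, W, C) feature maps. Convolutions go through
# C++ im2col plus BLAS gemm; depthwise convolutions have a dedicated kernel.

conv_out_hw <- function(hw, k, s, p) (hw + 2 * p - k) %/% s + 1L

# General (optionally grouped) 2-D convolution.
# w: (k*k*cin_per_group) x cout matrix, columns split into `groups` blocks;
# b: length-cout bias or NULL.
op_conv2d <- function(x, w, b = NULL, k, stride = 1L, pad = k %/% 2L, groups = 1L) {
  d <- dim(x$v)
  H <- d[1]; W <- d[2]; C <- d[3]
  cout <- ncol(w$v)
  if (C %% groups != 0L || cout %% groups != 0L)
    stop("channel count not divisible by group count", call. = FALSE)
  Ho <- conv_out_hw(H, k, stride, pad)
  Wo <- conv_out_hw(W, k, stride, pad)
  cols <- cpp_im2col(x$v, H, W, C, k, stride, pad)
  cig <- C %/% groups; cog <- cout %/% groups
  out <- matrix(0, Ho * Wo, cout)
  for (g in seq_len(groups)) {
    qi <- (g - 1L) * k * k * cig + seq_len(k * k * cig)
    oi <- (g - 1L) * cog + seq_len(cog)
    out[, oi] <- cols[, qi, drop = FALSE] %*% w$v[, oi, drop = FALSE]
  }
  if (!is.null(b)) out <- sweep(out, 2, b$v, "+")
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  y <- array(out, dim = c(Ho, Wo, cout))
  tns_op(y, parents, function(gr) {
    gm <- matrix(gr, Ho * Wo, cout)
    dw <- matrix(0, nrow(w$v), cout)
    dcols <- matrix(0, nrow(cols), ncol(cols))
    for (g in seq_len(groups)) {
      qi <- (g - 1L) * k * k * cig + seq_len(k * k * cig)
      oi <- (g - 1L) * cog + seq_len(cog)
      dw[, oi] <- crossprod(cols[, qi, drop = FALSE], gm[, oi, drop = FALSE])
      dcols[, qi] <- gm[, oi, drop = FALSE] %*% t(w$v[, oi, drop = FALSE])
    }
    dx <- array(cpp_col2im(dcols, H, W, C, k, stride, pad), dim = d)
    if (is.null(b)) list(dx, dw) else list(dx, dw, colSums(gm))
  })
}

# Depthwise k x k convolution; w is a (k, k, C) array, b length C or NULL.
op_dwconv <- function(x, w, b = NULL, k, stride = 1L, pad = k %/% 2L) {
  d <- dim(x$v)
  H <- d[1]; W <- d[2]; C <- d[3]
  Ho <- conv_out_hw(H, k, stride, pad)
  Wo <- conv_out_hw(W, k, stride, pad)
  y <- array(cpp_dwconv(x$v, w$v, H, W, C, k, stride, pad), dim = c(Ho, Wo, C))
  if (!is.null(b)) y <- y + chan_expand(y, b$v)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  tns_op(y, parents, function(gr) {
    bk <- cpp_dwconv_bwd(gr, x$v, w$v, H, W, C, k, stride, pad)
    dx <- array(bk$dx, dim = d)
    dw <- array(bk$dw, dim = c(k, k, C))
    if (is.null(b)) list(dx, dw)
    else list(dx, dw, colSums(matrix(gr, Ho * Wo, C)))
  })
}

op_maxpool <- function(x, k, stride = 1L, pad = k %/% 2L) {
  d <- dim(x$v)
  Ho <- conv_out_hw(d[1], k, stride, pad)
  Wo <- conv_out_hw(d[2], k, stride, pad)
  r <- cpp_maxpool(x$v, d[1], d[2], d[3], k, stride, pad)
  tns_op(array(r$y, dim = c(Ho, Wo, d[3])), list(x), function(g) {
    dx <- numeric(prod(d))
    s <- rowsum(as.numeric(g), r$idx)  # argmax indices may repeat
    dx[as.integer(rownames(s))] <- s
    list(array(dx, dim = d))
  })
}

# Fixed 3x3 box blur, stride 1, pad 1, zero padding counted in the divisor
# (divide by 9 everywhere). Used by the edge refiner's low-pass path.
op_boxblur3 <- function(x) {
  C <- dim(x$v)[3]
  w <- tensor(array(1 / 9, dim = c(3, 3, C)))
  op_dwconv(x, w, NULL, k = 3L, stride = 1L, pad = 1L)
}

# Adaptive average pooling to a g x g grid (reference-style window bounds:
# start = floor(i*H/g), end = ceil((i+1)*H/g)).
adapt_bounds <- function(n, g) {
  i <- 0:(g - 1)
  lo <- floor(i * n / g) + 1L
  hi <- ceiling((i + 1) * n / g)
  cbind(lo, hi)
}

op_adaptive_avgpool <- function(x, g) {
  if (g < 1) stop("pooled size must be positive", call. = FALSE)
  d <- dim(x$v)
  hb <- adapt_bounds(d[1], g)
  wb <- adapt_bounds(d[2], g)
  y <- array(0, dim = c(g, g, d[3]))
  for (i in seq_len(g)) for (j in seq_len(g)) {
    hs <- hb[i, 1]:hb[i, 2]; ws <- wb[j, 1]:wb[j, 2]
    y[i, j, ] <- colMeans(matrix(x$v[hs, ws, ], length(hs) * length(ws), d[3]))
  }
  tns_op(y, list(x), function(gr) {
    dx <- array(0, dim = d)
    for (i in seq_len(g)) for (j in seq_len(g)) {
      hs <- hb[i, 1]:hb[i, 2]; ws <- wb[j, 1]:wb[j, 2]
      npx <- length(hs) * length(ws)
      dx[hs, ws, ] <- dx[hs, ws, ] +
        array(rep(gr[i, j, ] / npx, each = npx), dim = c(length(hs), length(ws), d[3]))
    }
    list(dx)
  })
}

op_upsample2 <- function(x) {  # nearest-neighbour x2
  d <- dim(x$v)
  y <- x$v[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
  tns_op(y, list(x), function(g) {
    g1 <- g[seq(1, 2 * d[1], 2), , , drop = FALSE] + g[seq(2, 2 * d[1], 2), , , drop = FALSE]
    list(g1[, seq(1, 2 * d[2], 2), , drop = FALSE] + g1[, seq(2, 2 * d[2], 2), , drop = FALSE])
  })
}

# Bilinear interpolation matrix from n source to m target positions,
# half-pixel centres (no corner alignment): src = (dst + 0.5) * n/m - 0.5.
bilinear_matrix <- function(n, m) {
  A <- matrix(0, m, n)
  src <- (seq_len(m) - 0.5) * n / m - 0.5
  lo <- pmax(pmin(floor(src), n - 1), 0)
  frac <- pmin(pmax(src - lo, 0), 1)
  for (i in seq_len(m)) {
    l <- lo[i] + 1
    A[i, l] <- A[i, l] + (1 - frac[i])
    A[i, min(l + 1, n)] <- A[i, min(l + 1, n)] + frac[i]
  }
  A
}

op_bilinear <- function(x, Ho, Wo) {
  d <- dim(x$v)
  Ah <- bilinear_matrix(d[1], Ho)
  Aw <- bilinear_matrix(d[2], Wo)
  y <- array(0, dim = c(Ho, Wo, d[3]))
  for (c in seq_len(d[3])) y[, , c] <- Ah %*% x$v[, , c] %*% t(Aw)
  tns_op(y, list(x), function(g) {
    dx <- array(0, dim = d)
    for (c in seq_len(d[3])) dx[, , c] <- t(Ah) %*% g[, , c] %*% Aw
    list(dx)
  })
}
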