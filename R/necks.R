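# Feature-fusion necks. The improved neck is a single-sweep weighted
# bidirectional feature pyramid with stride-4 (P2) detail injection: all
# levels are compressed to a common width, a top-down pass propagates
# semantics (with a 3-conv refinement stack after the P4 fusion), the P3
# fusion additionally receives downsampled P2 detail, and a bottom-up pass
# restores the P4/P5 outputs. Fusion nodes use fast normalised fusion:
# sum(relu(w_i) * F_i) / (sum(relu(w_j)) + eps).

op_sadd <- function(a, c) tns_op(a$v + c, list(a), function(g) list(g))

op_ascale <- function(a, s) {  # array * scalar tensor
  tns_op(a$v * s$v, list(a, s), function(g) list(g * s$v, sum(g * a$v)))
}

fuse_maps <- function(xs, wparam, eps = 1e-4) {
  d1 <- dim(xs[[1]]$v)
  for (x in xs) {
    if (!identical(dim(x$v), d1)) stop("fusion inputs differ in shape", call. = FALSE)
  }
  r <- op_relu(wparam)
  inv <- op_recip(op_sadd(op_sum(r), eps))
  acc <- NULL
  for (i in seq_along(xs)) {
    term <- op_ascale(xs[[i]], op_index(r, i))
    acc <- if (is.null(acc)) term else op_add(acc, term)
  }
  op_ascale(acc, inv)
}

#' Fast normalised weighted fusion of feature maps
#'
#' Computes `sum(relu(w_i) * F_i) / (sum(relu(w_j)) + eps)`, the adaptive
#' fusion rule of weighted bidirectional feature pyramids: a convex-like
#' combination whose effective coefficients are nonnegative and sum to
#' slightly under one.
#'
#' @param inputs list of numeric arrays of identical shape.
#' @param weights numeric vector, one weight per input.
#' @param eps stabiliser in the denominator.
#' @return fused array of the common input shape.
#' @export
fast_normalized_fusion <- function(inputs, weights, eps = 1e-4) {
  if (length(inputs) < 2L) stop("fusion needs at least two inputs", call. = FALSE)
  if (length(weights) != length(inputs))
    stop("one weight per input required", call. = FALSE)
  with_no_grad(fuse_maps(lapply(inputs, tensor), tensor(weights), eps))$v
}

#' Construct the weighted bidirectional neck with P2 injection
#'
#' @param ch backbone channel widths of (P2, P3, P4, P5).
#' @param width common neck width (default 64 at nano scale).
#' @param eps fusion stabiliser.
#' @return a neck module mapping pyramid levels to refined (P3, P4, P5).
#' @export
bifpn <- function(ch = c(64L, 128L, 128L, 256L), width = 64L, eps = 1e-4) {
  w <- width
  new_module(
    "m_bifpn",
    children = list(
      cmp3 = m_conv(ch[2], w, 1L), cmp4 = m_conv(ch[3], w, 1L), cmp5 = m_conv(ch[4], w, 1L),
      down2 = m_conv(ch[1], w, 3L, stride = 2L),  # P2 detail, full conv
      td4 = m_seq(m_conv(w, w, 3L), m_conv(w, w, 1L), m_conv(w, w, 3L)),
      td3 = m_conv(w, w, 3L),
      down34 = m_seq(m_conv(w, w, 3L, stride = 2L, groups = w), m_conv(w, w, 1L)),
      out4 = m_conv(w, w, 3L),
      down45 = m_conv(w, w, 3L, stride = 2L),
      out5 = m_conv(w, w, 3L)),
    params = list(
      w_td4 = tensor(rep(1, 2), TRUE),
      w_td3 = tensor(rep(1, 3), TRUE),
      w_out4 = tensor(rep(1, 3), TRUE),
      w_out5 = tensor(rep(1, 2), TRUE)),
    width = w, eps = eps)
}

# x: list(p2, p3, p4, p5) of tensors
mod_forward.m_bifpn <- function(m, x, ...) {
  if (is.null(x$p2)) stop("the neck requires the P2 level", call. = FALSE)
  ch <- m$children
  p3 <- mod_forward(ch$cmp3, x$p3)
  p4 <- mod_forward(ch$cmp4, x$p4)
  p5 <- mod_forward(ch$cmp5, x$p5)
  p2d <- mod_forward(ch$down2, x$p2)
  p4td <- mod_forward(ch$td4, fuse_maps(list(p4, op_upsample2(p5)), m$params$w_td4, m$eps))
  p3out <- mod_forward(ch$td3,
                       fuse_maps(list(p3, op_upsample2(p4td), p2d), m$params$w_td3, m$eps))
  p4out <- mod_forward(ch$out4,
                       fuse_maps(list(p4, p4td, mod_forward(ch$down34, p3out)),
                                 m$params$w_out4, m$eps))
  p5out <- mod_forward(ch$out5,
                       fuse_maps(list(p5, mod_forward(ch$down45, p4out)),
                                 m$params$w_out5, m$eps))
  list(p3out, p4out, p5out)
}

mod_trace.m_bifpn <- function(m, shape) {
  # shape: list(p2, p3, p4, p5) of (H, W, C)
  ch <- m$children
  macs <- mod_trace(ch$cmp3, shape$p3)$macs + mod_trace(ch$cmp4, shape$p4)$macs +
    mod_trace(ch$cmp5, shape$p5)$macs + mod_trace(ch$down2, shape$p2)$macs
  s3 <- c(shape$p3[1], shape$p3[2], m$width)
  s4 <- c(shape$p4[1], shape$p4[2], m$width)
  s5 <- c(shape$p5[1], shape$p5[2], m$width)
  macs <- macs + mod_trace(ch$td4, s4)$macs + mod_trace(ch$td3, s3)$macs +
    mod_trace(ch$down34, s3)$macs + mod_trace(ch$out4, s4)$macs +
    mod_trace(ch$down45, s4)$macs + mod_trace(ch$out5, s5)$macs
  list(shape = list(s3, s4, s5), macs = macs)
}

#' Run the bidirectional neck on a feature pyramid
#'
#' @param neck module from [bifpn()].
#' @param levels named list of numeric (H, W, C) arrays `p2, p3, p4, p5` at
#'   strides 4/8/16/32.
#' @return list of refined arrays `(P3', P4', P5')` at strides 8/16/32.
#' @export
bifpn_neck <- function(neck, levels) {
  stopifnot(inherits(neck, "m_bifpn"))
  out <- with_no_grad(mod_forward(neck, lapply(levels, tensor)))
  lapply(out, function(o) o$v)
}

# ---- baseline path-aggregation neck ----------------------------------------

m_pafpn <- function() {
  new_module("m_pafpn",
             children = list(
               c13 = m_c3k2(384L, 128L), c16 = m_c3k2(256L, 64L),
               cv17 = m_conv(64L, 64L, 3L, stride = 2L),
               c19 = m_c3k2(192L, 128L),
               cv20 = m_conv(128L, 128L, 3L, stride = 2L),
               c22 = m_c3k2(384L, 256L, c3k = TRUE)))
}

mod_forward.m_pafpn <- function(m, x, ...) {
  ch <- m$children
  t13 <- mod_forward(ch$c13, op_concat_c(list(op_upsample2(x$p5), x$p4)))
  t16 <- mod_forward(ch$c16, op_concat_c(list(op_upsample2(t13), x$p3)))
  t19 <- mod_forward(ch$c19, op_concat_c(list(mod_forward(ch$cv17, t16), t13)))
  t22 <- mod_forward(ch$c22, op_concat_c(list(mod_forward(ch$cv20, t19), x$p5)))
  list(t16, t19, t22)
}

mod_trace.m_pafpn <- function(m, shape) {
  ch <- m$children
  s3 <- shape$p3; s4 <- shape$p4; s5 <- shape$p5
  t13 <- mod_trace(ch$c13, c(s4[1], s4[2], s5[3] + s4[3]))
  t16 <- mod_trace(ch$c16, c(s3[1], s3[2], t13$shape[3] + s3[3]))
  t17 <- mod_trace(ch$cv17, t16$shape)
  t19 <- mod_trace(ch$c19, c(s4[1], s4[2], t17$shape[3] + t13$shape[3]))
  t20 <- mod_trace(ch$cv20, t19$shape)
  t22 <- mod_trace(ch$c22, c(s5[1], s5[2], t20$shape[3] + s5[3]))
  list(shape = list(t16$shape, t19$shape, t22$shape),
       macs = t13$macs + t16$macs + t17$macs + t19$macs + t20$macs + t22$macs)
}

# neck variant with MERCA substituted for the CSP blocks (placement study)
m_pafpn_merca <- function() {
  n <- m_pafpn()
  n$children$c13 <- merca(384L, 128L)
  n$children$c16 <- merca(256L, 64L)
  n$children$c19 <- merca(192L, 128L)
  n$children$c22 <- merca(384L, 256L)
  n
}
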