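# Multi-scale Edge-Refinement Context Aggregator (MERCA).
#
# The block replaces a CSP bottleneck stage in the backbone. Input features are
# mapped to a parameterised scale pyramid by adaptive average pooling (pooled
# grid sizes g_k = 3k, k = 1..4 by default); each pooled map passes a scale
# adapter (1x1 reduction conv then grouped 3x3 conv), an edge refiner
# X + Conv(X - boxblur(X)), and is rescaled back to the input resolution by
# bilinear interpolation. The rescaled branches are concatenated with a local
# 1x1 branch at full resolution (CSP-style: 4 branches at C_out/4 channels
# plus the local C_out channels = 2*C_out) and merged by a 1x1 aggregation
# conv back to C_out channels.

#' Construct a MERCA block
#'
#' @param cin,cout input/output channel counts.
#' @param scales pooled grid sizes of the scale pyramid (strictly increasing).
#' @param group_width channels per group of the grouped 3x3 scale conv
#'   (default 1, i.e. depthwise).
#' @param er_group_width channels per group of the edge-refiner conv.
#' @param act activation of the adapter convs (`"silu"` or `"none"`).
#' @return a MERCA module usable with [merca_forward()].
#' @export
merca <- function(cin, cout, scales = c(3L, 6L, 9L, 12L),
                  group_width = 1L, er_group_width = 2L,
                  act = c("silu", "none")) {
  act <- match.arg(act)
  if (any(diff(scales) <= 0) || any(scales < 1))
    stop("scales must be strictly increasing and >= 1", call. = FALSE)
  b <- cout %/% length(scales)
  if (b * length(scales) != cout)
    stop("output channels must be divisible by the branch count", call. = FALSE)
  if (b %% group_width != 0L || b %% er_group_width != 0L)
    stop("branch width not divisible by group width", call. = FALSE)
  ch <- list()
  for (k in seq_along(scales)) {
    ch[[paste0("red", k)]] <- m_conv(cin, b, 1L, act = act)
    ch[[paste0("scl", k)]] <- m_conv(b, b, 3L, groups = b %/% group_width, act = act)
    # Eq-style linear edge conv: the residual form X + Conv(X - blur(X)) is
    # exact on constants only when the conv path is linear.
    ch[[paste0("er", k)]] <- m_conv(b, b, 3L, groups = b %/% er_group_width, act = "none")
  }
  ch$local <- m_conv(cin, cout, 1L, act = act)
  ch$agg <- m_conv(2L * cout, cout, 1L, act = act)
  new_module("m_merca", children = ch,
             cin = cin, cout = cout, scales = as.integer(scales), b = b)
}

# clamp pooled sizes to the input resolution; duplicates are kept (each branch
# owns distinct parameters and the aggregation conv expects all of them)
merca_eff_scales <- function(m, H, W) {
  pmin(m$scales, min(H, W))
}

# scale adapter A_k: adaptive pool to g x g, 1x1 reduction, grouped 3x3
merca_adapter_t <- function(m, x, k, g) {
  p <- op_adaptive_avgpool(x, g)
  mod_forward(m$children[[paste0("scl", k)]],
              mod_forward(m$children[[paste0("red", k)]], p))
}

# edge refiner ER(X) = X + Conv(X - P_avg(X)) with a 3x3/9 zero-pad box blur
merca_refine_t <- function(m, x, k) {
  hf <- op_sub(x, op_boxblur3(x))
  op_add(x, mod_forward(m$children[[paste0("er", k)]], hf))
}

mod_forward.m_merca <- function(m, x, ...) {
  d <- dim(x$v)
  gs <- merca_eff_scales(m, d[1], d[2])
  branches <- vector("list", length(gs))
  for (k in seq_along(gs)) {
    a <- merca_adapter_t(m, x, k, gs[k])
    r <- merca_refine_t(m, a, k)
    branches[[k]] <- op_bilinear(r, d[1], d[2])
  }
  loc <- mod_forward(m$children$local, x)
  mod_forward(m$children$agg, op_concat_c(c(list(loc), branches)))
}

mod_trace.m_merca <- function(m, shape) {
  gs <- merca_eff_scales(m, shape[1], shape[2])
  macs <- 0
  for (k in seq_along(gs)) {
    g <- gs[k]
    macs <- macs + mod_trace(m$children[[paste0("red", k)]], c(g, g, m$cin))$macs +
      mod_trace(m$children[[paste0("scl", k)]], c(g, g, m$b))$macs +
      mod_trace(m$children[[paste0("er", k)]], c(g, g, m$b))$macs
  }
  macs <- macs + mod_trace(m$children$local, shape)$macs +
    mod_trace(m$children$agg, c(shape[1], shape[2], 2L * m$cout))$macs
  list(shape = c(shape[1], shape[2], m$cout), macs = macs)
}

#' Run one MERCA scale-adapter branch
#'
#' Adaptive average pooling to a `g` x `g` grid followed by the branch's 1x1
#' reduction conv and grouped 3x3 conv.
#'
#' @param block a module from [merca()].
#' @param x numeric (H, W, C) array.
#' @param g pooled output size (clamped to `min(H, W)`).
#' @param k branch index whose parameters are used.
#' @return numeric (g, g, branch-width) array.
#' @export
scale_adapter <- function(block, x, g, k = 1L) {
  stopifnot(inherits(block, "m_merca"))
  if (g < 1) stop("pooled size must be positive", call. = FALSE)
  g <- min(g, dim(x)[1], dim(x)[2])
  with_no_grad(merca_adapter_t(block, tensor(x), k, g))$v
}

#' Apply the MERCA edge refiner
#'
#' Computes `X + Conv(X - P_avg(X))`: a 3x3 stride-1 box blur (zero padding
#' counted in the divisor) isolates low frequencies, the difference is the
#' high-frequency edge residual, and a linear grouped 3x3 conv re-injects it
#' onto the input.
#'
#' @inheritParams scale_adapter
#' @param x numeric (H, W, branch-width) array.
#' @return array of the same shape as `x`.
#' @export
edge_refine <- function(block, x, k = 1L) {
  stopifnot(inherits(block, "m_merca"))
  with_no_grad(merca_refine_t(block, tensor(x), k))$v
}

#' Forward pass through a MERCA block
#'
#' @param block a module from [merca()].
#' @param x numeric (H, W, cin) array.
#' @return numeric (H, W, cout) array.
#' @export
merca_forward <- function(block, x) {
  stopifnot(inherits(block, "m_merca"))
  with_no_grad(mod_forward(block, tensor(x)))$v
}
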