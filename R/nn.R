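# Minimal module system: a module is a list with named `children` (sub-modules)
# and `params` (leaf tensors), plus whatever config its forward needs.
# `mod_forward()` runs the computation on tensors; `mod_trace()` propagates a
# (H, W, C) shape analytically and returns output shape and multiply-accumulate
# counts without touching any data.

new_module <- function(cls, children = list(), params = list(), ...) {
  structure(list(children = children, params = params, ...),
            class = c(cls, "lmtb_module"))
}

mod_forward <- function(m, x, ...) UseMethod("mod_forward")

mod_trace <- function(m, shape) UseMethod("mod_trace")

#' Collect the trainable parameters of a module tree
#'
#' @param m a module.
#' @param prefix name prefix used during recursion.
#' @return named list of leaf tensors.
#' @keywords internal
mod_params <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params)) out[[paste0(prefix, nm)]] <- m$params[[nm]]
  for (nm in names(m$children)) {
    out <- c(out, mod_params(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

n_params <- function(m) {
  sum(vapply(mod_params(m), function(p) length(p$v), numeric(1)))
}

# He-style initialisation for SiLU stacks; biases start at zero.
init_w <- function(n, fan_in) {
  stats::rnorm(n, sd = sqrt(2 / fan_in))
}

# ---- conv block: fused conv + bias + activation ----------------------------

m_conv <- function(cin, cout, k = 1L, stride = 1L, groups = 1L,
                   act = c("silu", "none"), pad = k %/% 2L) {
  act <- match.arg(act)
  if (cin %% groups != 0L || cout %% groups != 0L)
    stop("channel count not divisible by group count", call. = FALSE)
  dw <- groups == cin && cin == cout
  fan <- k * k * cin %/% groups
  w <- if (dw) tensor(array(init_w(k * k * cin, fan), dim = c(k, k, cin)), TRUE)
       else tensor(matrix(init_w(fan * cout, fan), fan, cout), TRUE)
  b <- tensor(numeric(cout), TRUE)
  new_module("m_conv", params = list(w = w, b = b),
             cin = cin, cout = cout, k = k, stride = stride, pad = pad,
             groups = groups, act = act, dw = dw)
}

mod_forward.m_conv <- function(m, x, ...) {
  y <- if (m$dw) op_dwconv(x, m$params$w, m$params$b, m$k, m$stride, m$pad)
       else op_conv2d(x, m$params$w, m$params$b, m$k, m$stride, m$pad, m$groups)
  if (m$act == "silu") op_silu(y) else y
}

mod_trace.m_conv <- function(m, shape) {
  ho <- conv_out_hw(shape[1], m$k, m$stride, m$pad)
  wo <- conv_out_hw(shape[2], m$k, m$stride, m$pad)
  list(shape = c(ho, wo, m$cout),
       macs = as.numeric(m$k)^2 * (m$cin / m$groups) * m$cout * ho * wo)
}

# Closed-form parameter count of one fused conv: k^2 * cin/g * cout + cout.
conv_param_formula <- function(cin, cout, k = 1, groups = 1) {
  k^2 * cin / groups * cout + cout
}

# ---- containers ------------------------------------------------------------

m_seq <- function(...) {
  ch <- list(...)
  if (is.null(names(ch)) || any(names(ch) == ""))
    names(ch) <- paste0("s", seq_along(ch))
  new_module("m_seq", children = ch)
}

mod_forward.m_seq <- function(m, x, ...) {
  for (ch in m$children) x <- mod_forward(ch, x)
  x
}

mod_trace.m_seq <- function(m, shape) {
  macs <- 0
  for (ch in m$children) {
    tr <- mod_trace(ch, shape)
    shape <- tr$shape
    macs <- macs + tr$macs
  }
  list(shape = shape, macs = macs)
}

m_upsample2 <- function() new_module("m_upsample2")
mod_forward.m_upsample2 <- function(m, x, ...) op_upsample2(x)
mod_trace.m_upsample2 <- function(m, shape) {
  list(shape = c(shape[1] * 2L, shape[2] * 2L, shape[3]), macs = 0)
}
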