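#' @useDynLib lmtb, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Tape-based reverse-mode autodiff. A tensor is an environment holding the
# value (`v`, a numeric vector/matrix/array), an accumulated gradient (`grad`),
# the parent tensors it was computed from, and a backward closure mapping the
# output gradient to a list of parent gradients. Node ids increase
# monotonically along the tape, so reverse-id order is a topological order.

.tape <- new.env(parent = emptyenv())
.tape$id <- 0L

#' Create a tensor
#'
#' Wraps a numeric value for use with the package's reverse-mode autodiff.
#' Leaf tensors with `requires_grad = TRUE` are trainable parameters.
#'
#' @param v numeric vector, matrix or array.
#' @param requires_grad should gradients be accumulated into this leaf?
#' @return an object of class `lmtb_tensor`.
#' @keywords internal
tensor <- function(v, requires_grad = FALSE) {
  new_tensor(v, parents = list(), bw = NULL, rg = requires_grad)
}

new_tensor <- function(v, parents, bw, rg = NA) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$parents <- parents
  e$bw <- bw
  e$rg <- if (is.na(rg)) any(vapply(parents, function(p) p$rg, logical(1))) else rg
  .tape$id <- .tape$id + 1L
  e$id <- .tape$id
  class(e) <- "lmtb_tensor"
  e
}

is_tensor <- function(x) inherits(x, "lmtb_tensor")

#' @export
print.lmtb_tensor <- function(x, ...) {
  d <- dim(x$v)
  cat("<tensor", if (is.null(d)) length(x$v) else paste(d, collapse = "x"),
      if (x$rg) "grad" else "", ">\n")
  invisible(x)
}

# Emit a non-leaf node; parents that do not require grad are kept so backward
# closures can index positionally, but no gradient is pushed into them.
# Under `with_no_grad()` the tape is not extended (and forward intermediates
# captured by backward closures are not retained).
.tape$grad_on <- TRUE

tns_op <- function(v, parents, bw) {
  if (!.tape$grad_on) return(new_tensor(v, list(), NULL, rg = FALSE))
  new_tensor(v, parents, bw)
}

with_no_grad <- function(expr) {
  old <- .tape$grad_on
  .tape$grad_on <- FALSE
  on.exit(.tape$grad_on <- old)
  expr
}

#' Run reverse-mode backpropagation from a scalar (or seeded) root
#'
#' @param root output tensor.
#' @param seed gradient to seed at the root; defaults to 1 for scalars.
#' @keywords internal
backward <- function(root, seed = NULL) {
  if (is.null(seed)) {
    stopifnot(length(root$v) == 1L)
    seed <- 1
  }
  root$grad <- seed
  # collect reachable nodes
  nodes <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(nodes[[key]])) next
    nodes[[key]] <- n
    if (n$rg) for (p in n$parents) if (p$rg) stack[[length(stack) + 1L]] <- p
  }
  ord <- sort(as.integer(ls(nodes)), decreasing = TRUE)
  for (id in ord) {
    n <- nodes[[as.character(id)]]
    if (is.null(n$bw) || is.null(n$grad)) next
    gs <- n$bw(n$grad)
    for (i in seq_along(gs)) {
      p <- n$parents[[i]]
      if (!p$rg || is.null(gs[[i]])) next
      p$grad <- if (is.null(p$grad)) gs[[i]] else p$grad + gs[[i]]
    }
    if (length(n$parents)) n$grad <- NULL  # free non-leaf grads early
  }
  invisible(root)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise primitives ------------------------------------------------

op_add <- function(a, b) {
  tns_op(a$v + b$v, list(a, b), function(g) list(g, g))
}

op_sub <- function(a, b) {
  tns_op(a$v - b$v, list(a, b), function(g) list(g, -g))
}

op_mul <- function(a, b) {
  tns_op(a$v * b$v, list(a, b), function(g) list(g * b$v, g * a$v))
}

op_smul <- function(a, s) {  # multiply by plain numeric constant
  tns_op(a$v * s, list(a), function(g) list(g * s))
}

op_tanh <- function(a) {
  t <- tanh(a$v)
  tns_op(t, list(a), function(g) list(g * (1 - t * t)))
}

op_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  tns_op(s, list(a), function(g) list(g * s * (1 - s)))
}

op_silu <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  tns_op(a$v * s, list(a), function(g) list(g * s * (1 + a$v * (1 - s))))
}

op_relu <- function(a) {
  m <- a$v > 0
  tns_op(a$v * m, list(a), function(g) list(g * m))
}

op_square <- function(a) {
  tns_op(a$v * a$v, list(a), function(g) list(2 * g * a$v))
}

op_sqrt_eps <- function(a, eps) {
  r <- sqrt(a$v + eps)
  tns_op(r, list(a), function(g) list(g / (2 * r)))
}

op_recip <- function(a) {
  r <- 1 / a$v
  tns_op(r, list(a), function(g) list(-g * r * r))
}

op_sum <- function(a) {
  tns_op(sum(a$v), list(a), function(g) {
    gv <- if (is.null(dim(a$v))) rep(g, length(a$v)) else array(g, dim = dim(a$v))
    list(gv)
  })
}

op_mean <- function(a) op_smul(op_sum(a), 1 / length(a$v))

op_index <- function(a, i) {  # scalar element of a vector parameter
  tns_op(a$v[i], list(a), function(g) {
    gv <- numeric(length(a$v))
    gv[i] <- g
    list(gv)
  })
}

# ---- per-channel broadcast over (H, W, C) maps or (n, C) token matrices ----

chan_expand <- function(x, s) {
  if (is.matrix(x)) rep(s, each = nrow(x)) else rep(s, each = prod(dim(x)[1:2]))
}

chan_reduce <- function(x, g) {
  if (is.matrix(x)) colSums(g)
  else colSums(matrix(g, prod(dim(x)[1:2]), dim(x)[3]))
}

op_cscale <- function(a, s) {  # s: length-C parameter, per-channel scale
  sv <- chan_expand(a$v, s$v)
  tns_op(a$v * sv, list(a, s), function(g) {
    list(g * sv, chan_reduce(a$v, g * a$v))
  })
}

op_cshift <- function(a, s) {  # s: length-C parameter, per-channel shift
  tns_op(a$v + chan_expand(a$v, s$v), list(a, s), function(g) {
    list(g, chan_reduce(a$v, g))
  })
}

# ---- channel concat / slice on (H, W, C) arrays ----------------------------

op_concat_c <- function(xs) {
  vs <- lapply(xs, function(x) x$v)
  d1 <- dim(vs[[1]])
  cs <- vapply(vs, function(v) dim(v)[3], numeric(1))
  out <- array(0, dim = c(d1[1], d1[2], sum(cs)))
  at <- 0L
  for (v in vs) {
    out[, , at + seq_len(dim(v)[3])] <- v
    at <- at + dim(v)[3]
  }
  tns_op(out, xs, function(g) {
    res <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      res[[i]] <- g[, , at + seq_len(cs[i]), drop = FALSE]
      at <- at + cs[i]
    }
    res
  })
}

op_slice_c <- function(a, from, to) {
  tns_op(a$v[, , from:to, drop = FALSE], list(a), function(g) {
    gv <- array(0, dim = dim(a$v))
    gv[, , from:to] <- g
    list(gv)
  })
}

# ---- matrix ops for token attention ----------------------------------------

op_matmul <- function(a, b) {
  tns_op(a$v %*% b$v, list(a, b), function(g) {
    list(g %*% t(b$v), t(a$v) %*% g)
  })
}

op_addrow <- function(a, b) {  # add vector b across rows of matrix a
  tns_op(sweep(a$v, 2, b$v, "+"), list(a, b), function(g) list(g, colSums(g)))
}

op_rowscale <- function(a, s) {  # scale row i of matrix a by s[i]
  tns_op(a$v * s$v, list(a, s), function(g) {
    list(g * s$v, rowSums(g * a$v))
  })
}

op_colscale <- function(a, s) {  # scale column j of matrix a by s[j]
  sv <- rep(s$v, each = nrow(a$v))
  tns_op(a$v * sv, list(a, s), function(g) {
    list(g * sv, colSums(g * a$v))
  })
}

op_slice_cols <- function(a, from, to) {
  tns_op(a$v[, from:to, drop = FALSE], list(a), function(g) {
    gv <- matrix(0, nrow(a$v), ncol(a$v))
    gv[, from:to] <- g
    list(gv)
  })
}

op_rowsum <- function(a) {  # matrix -> vector of row sums
  tns_op(rowSums(a$v), list(a), function(g) list(matrix(g, nrow(a$v), ncol(a$v))))
}

op_colsum <- function(a) {  # matrix -> vector of column sums
  tns_op(colSums(a$v), list(a), function(g) {
    list(matrix(g, nrow(a$v), ncol(a$v), byrow = TRUE))
  })
}

op_softmax <- function(a) {  # vector softmax
  z <- a$v - max(a$v)
  e <- exp(z)
  s <- e / sum(e)
  tns_op(s, list(a), function(g) list(s * (g - sum(g * s))))
}

# (H, W, C) <-> (n = H*W, C) reshapes are free: memory layout is identical.
op_tokens <- function(a) {
  d <- dim(a$v)
  tns_op(matrix(a$v, d[1] * d[2], d[3]), list(a),
         function(g) list(array(g, dim = d)))
}

op_untokens <- function(a, H, W) {
  tns_op(array(a$v, dim = c(H, W, ncol(a$v))), list(a),
         function(g) list(matrix(g, H * W, ncol(a$v))))
}
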