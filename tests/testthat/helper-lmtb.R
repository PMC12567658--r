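# shared test utilities

# central-difference check of tape gradients for one parameter tensor.
# build_loss() must rebuild the loss from the current parameter values.
expect_grad_matches <- function(build_loss, param, n_checks = 6, eps = 1e-5,
                                tol = 1e-4) {
  lmtb:::zero_grads(list(param))
  l <- build_loss()
  lmtb:::backward(l)
  g <- param$grad
  expect_false(is.null(g))
  idx <- sample.int(length(param$v), min(n_checks, length(param$v)))
  for (i in idx) {
    old <- param$v[i]
    param$v[i] <- old + eps
    lp <- build_loss()$v
    param$v[i] <- old - eps
    lm <- build_loss()$v
    param$v[i] <- old
    num <- (lp - lm) / (2 * eps)
    expect_equal(as.numeric(g[i]), num, tolerance = tol)
  }
}

# scalar sum-of-squares loss over a tensor
sq_loss <- function(t) lmtb:::op_sum(lmtb:::op_square(t))

rand_map <- function(H, W, C, sd = 1) array(rnorm(H * W * C, sd = sd), dim = c(H, W, C))

# detection/ground-truth data-frame helpers
det_df <- function(conf, cx, cy, w, h, class = 0L, image = 1L) {
  if (!length(conf)) {
    return(data.frame(image = integer(0), class = integer(0), conf = numeric(0),
                      cx = numeric(0), cy = numeric(0), w = numeric(0),
                      h = numeric(0)))
  }
  data.frame(image = image, class = class, conf = conf,
             cx = cx, cy = cy, w = w, h = h)
}

gt_df <- function(cx, cy, w, h, class = 0L, image = 1L) {
  data.frame(image = image, class = class, cx = cx, cy = cy, w = w, h = h)
}

# brute-force per-window-mean adaptive average pooling oracle
adaptive_pool_oracle <- function(x, g) {
  d <- dim(x)
  out <- array(0, dim = c(g, g, d[3]))
  for (i in 1:g) {
    hs <- (floor((i - 1) * d[1] / g) + 1):ceiling(i * d[1] / g)
    for (j in 1:g) {
      ws <- (floor((j - 1) * d[2] / g) + 1):ceiling(j * d[2] / g)
      for (c in seq_len(d[3])) out[i, j, c] <- mean(x[hs, ws, c])
    }
  }
  out
}
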