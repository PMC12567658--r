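# Weighted bidirectional neck: fusion rule, shapes, parameter economy.

test_that("fast normalised fusion reduces to the mean for equal weights", {
  set.seed(41)
  a <- rand_map(4, 4, 2)
  b <- rand_map(4, 4, 2)
  out <- fast_normalized_fusion(list(a, b), c(1, 1), eps = 1e-12)
  expect_equal(out, (a + b) / 2, tolerance = 1e-9)
})

test_that("a zero weight removes its input from the fusion", {
  set.seed(42)
  a <- rand_map(3, 3, 2)
  b <- rand_map(3, 3, 2)
  out <- fast_normalized_fusion(list(a, b), c(0, 2), eps = 1e-12)
  expect_equal(out, b, tolerance = 1e-9)
})

test_that("fusion output lies within the elementwise input envelope", {
  set.seed(43)
  for (trial in 1:10) {
    m <- sample(2:4, 1)
    xs <- lapply(seq_len(m), function(i) rand_map(5, 5, 3))
    w <- runif(m, 0, 3)
    eps <- 1e-4
    out <- fast_normalized_fusion(xs, w, eps)
    s <- sum(w) / (sum(w) + eps)  # epsilon shrinkage factor
    lo <- do.call(pmin, xs)
    hi <- do.call(pmax, xs)
    expect_true(all(out >= pmin(lo * s, hi * s) - 1e-12))
    expect_true(all(out <= pmax(lo * s, hi * s) + 1e-12))
  }
})

test_that("fusion validates shapes and weight counts", {
  a <- rand_map(4, 4, 2)
  expect_error(fast_normalized_fusion(list(a), 1), "at least two")
  expect_error(fast_normalized_fusion(list(a, rand_map(3, 3, 2)), c(1, 1)),
               "differ in shape")
  expect_error(fast_normalized_fusion(list(a, a), c(1, 1, 1)), "one weight per input")
})

test_that("neck outputs sit at strides 8/16/32 and require P2", {
  set.seed(44)
  nk <- bifpn()
  S <- 64L
  levels <- list(p2 = lmtb:::tensor(rand_map(S / 4, S / 4, 64)),
                 p3 = lmtb:::tensor(rand_map(S / 8, S / 8, 128)),
                 p4 = lmtb:::tensor(rand_map(S / 16, S / 16, 128)),
                 p5 = lmtb:::tensor(rand_map(S / 32, S / 32, 256)))
  out <- lmtb:::with_no_grad(lmtb:::mod_forward(nk, levels))
  expect_equal(dim(out[[1]]$v), c(S / 8, S / 8, 64L))
  expect_equal(dim(out[[2]]$v), c(S / 16, S / 16, 64L))
  expect_equal(dim(out[[3]]$v), c(S / 32, S / 32, 64L))
  expect_error(lmtb:::mod_forward(nk, levels[c("p3", "p4", "p5")]),
               "requires the P2 level")
})

test_that("the array-level neck wrapper matches the module forward", {
  set.seed(47)
  nk <- bifpn()
  levels <- list(p2 = rand_map(16, 16, 64), p3 = rand_map(8, 8, 128),
                 p4 = rand_map(4, 4, 128), p5 = rand_map(2, 2, 256))
  out <- bifpn_neck(nk, levels)
  expect_length(out, 3L)
  ref <- lmtb:::with_no_grad(lmtb:::mod_forward(nk, lapply(levels, lmtb:::tensor)))
  for (i in 1:3) expect_identical(out[[i]], ref[[i]]$v)
})

test_that("an all-zero pyramid yields all-zero outputs", {
  nk <- bifpn()
  z <- function(s, c) lmtb:::tensor(array(0, dim = c(s, s, c)))
  out <- lmtb:::with_no_grad(lmtb:::mod_forward(
    nk, list(p2 = z(16, 64), p3 = z(8, 128), p4 = z(4, 128), p5 = z(2, 256))))
  for (o in out) expect_equal(max(abs(o$v)), 0)
})

test_that("running a width-matched neck on the outputs preserves shapes", {
  set.seed(45)
  nk <- bifpn()
  nk2 <- bifpn(ch = c(64L, 64L, 64L, 64L))
  S <- 64L
  levels <- list(p2 = lmtb:::tensor(rand_map(S / 4, S / 4, 64)),
                 p3 = lmtb:::tensor(rand_map(S / 8, S / 8, 128)),
                 p4 = lmtb:::tensor(rand_map(S / 16, S / 16, 128)),
                 p5 = lmtb:::tensor(rand_map(S / 32, S / 32, 256)))
  o1 <- lmtb:::with_no_grad(lmtb:::mod_forward(nk, levels))
  # re-derive a P2-scale map and run again: spatial shapes are unchanged
  p2b <- lmtb:::with_no_grad(lmtb:::op_upsample2(o1[[1]]))
  o2 <- lmtb:::with_no_grad(lmtb:::mod_forward(
    nk2, list(p2 = p2b, p3 = o1[[1]], p4 = o1[[2]], p5 = o1[[3]])))
  for (i in 1:3) expect_identical(dim(o2[[i]]$v), dim(o1[[i]]$v))
})

test_that("neck parameters follow the closed form and undercut the baseline neck", {
  nk <- bifpn()
  cf <- lmtb:::conv_param_formula
  w <- 64
  oracle <- cf(128, w, 1) + cf(128, w, 1) + cf(256, w, 1) +  # compressions
    cf(64, w, 3) +                                            # P2 downsample
    cf(w, w, 3) + cf(w, w, 1) + cf(w, w, 3) +                 # 3-conv P4 stack
    cf(w, w, 3) +                                             # P3 node conv
    cf(w, w, 3, groups = w) + cf(w, w, 1) +                   # separable down
    cf(w, w, 3) + cf(w, w, 3) + cf(w, w, 3) +                 # P4 out, down, P5 out
    2 + 3 + 3 + 2                                             # fusion weights
  expect_identical(lmtb:::n_params(nk), oracle)
  expect_lt(lmtb:::n_params(nk), lmtb:::n_params(lmtb:::m_pafpn()))
})

test_that("every fusion weight receives gradient", {
  set.seed(46)
  nk <- bifpn()
  levels <- list(p2 = lmtb:::tensor(rand_map(16, 16, 64)),
                 p3 = lmtb:::tensor(rand_map(8, 8, 128)),
                 p4 = lmtb:::tensor(rand_map(4, 4, 128)),
                 p5 = lmtb:::tensor(rand_map(2, 2, 256)))
  params <- lmtb:::mod_params(nk)
  lmtb:::zero_grads(params)
  out <- lmtb:::mod_forward(nk, levels)
  loss <- lmtb:::op_add(lmtb:::op_add(sq_loss(out[[1]]), sq_loss(out[[2]])),
                        sq_loss(out[[3]]))
  lmtb:::backward(loss)
  for (nm in grep("^w_", names(params), value = TRUE)) {
    g <- params[[nm]]$grad
    expect_false(is.null(g), info = nm)
    expect_gt(max(abs(g)), 0, label = paste("grad of", nm))
  }
  # normalised coefficients are nonnegative and sum to just under one
  for (nm in grep("^w_", names(params), value = TRUE)) {
    wv <- pmax(params[[nm]]$v, 0)
    coef <- wv / (sum(wv) + 1e-4)
    expect_true(all(coef >= 0))
    expect_lt(sum(coef), 1)
  }
})
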