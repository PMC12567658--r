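# IoU matching, precision/recall, average precision.

test_that("perfect detections give TP = |gts|, FP = 0, FN = 0", {
  g <- gt_df(cx = c(0.2, 0.5, 0.8), cy = c(0.2, 0.5, 0.8),
             w = rep(0.1, 3), h = rep(0.1, 3))
  d <- det_df(conf = c(0.9, 0.8, 0.7), cx = g$cx, cy = g$cy, w = g$w, h = g$h)
  m <- match_detections(d, g, 0.5)
  expect_identical(m, list(TP = 3L, FP = 0L, FN = 0L))
  expect_equal(mean_average_precision(d, g, 0.5), 1.0)
  expect_equal(mean_average_precision(d, g, seq(0.5, 0.95, 0.05)), 1.0)
})

test_that("no detections give TP = 0 and FN = |gts|; empty inputs behave", {
  g <- gt_df(cx = c(0.3, 0.6), cy = c(0.3, 0.6), w = c(0.1, 0.1), h = c(0.1, 0.1))
  d <- det_df(conf = numeric(0), cx = numeric(0), cy = numeric(0),
              w = numeric(0), h = numeric(0))
  m <- match_detections(d, g, 0.5)
  expect_identical(m$TP, 0L)
  expect_identical(m$FN, 2L)
  expect_equal(mean_average_precision(d, g, 0.5), 0.0)
})

test_that("greedy matching agrees with the exhaustive assignment oracle", {
  # 3 gts, 4 dets with overlapping candidates
  g <- gt_df(cx = c(0.30, 0.40, 0.70), cy = c(0.30, 0.40, 0.70),
             w = rep(0.20, 3), h = rep(0.20, 3))
  d <- det_df(conf = c(0.95, 0.90, 0.85, 0.80),
              cx = c(0.31, 0.33, 0.70, 0.41),
              cy = c(0.31, 0.33, 0.71, 0.41),
              w = rep(0.20, 4), h = rep(0.20, 4))
  m <- match_detections(d, g, 0.5)

  # oracle: maximise the number of one-to-one pairs with IoU >= t over all
  # injective det -> gt assignments
  iou <- box_iou(as.matrix(d[, c("cx", "cy", "w", "h")]),
                 as.matrix(g[, c("cx", "cy", "w", "h")]))
  best <- 0L
  assigns <- expand.grid(rep(list(0:3), 4))
  for (r in seq_len(nrow(assigns))) {
    a <- as.integer(assigns[r, ])
    used <- a[a > 0]
    if (anyDuplicated(used)) next
    ok <- all(vapply(seq_len(4), function(i) {
      a[i] == 0L || iou[i, a[i]] >= 0.5
    }, logical(1)))
    if (ok) best <- max(best, length(used))
  }
  expect_identical(m$TP, best)
})

test_that("precision and recall follow the defining ratios with 0/0 = 0", {
  pr <- precision_recall(2, 1, 0)
  expect_equal(pr$P, 2 / 3)
  pr <- precision_recall(2, 0, 1)
  expect_equal(pr$R, 2 / 3)
  expect_identical(precision_recall(0, 0, 0), list(P = 0, R = 0))
  expect_error(precision_recall(-1, 0, 0), "nonnegative")
  expect_error(match_detections(det_df(0.5, 0.5, 0.5, -0.1, 0.1),
                                gt_df(0.5, 0.5, 0.1, 0.1)), "malformed")
})

test_that("AP equals the hand-integrated value on the fixed 5-det/3-gt case", {
  g <- gt_df(cx = c(0.2, 0.5, 0.8), cy = c(0.2, 0.5, 0.8),
             w = rep(0.1, 3), h = rep(0.1, 3))
  d <- det_df(conf = c(0.9, 0.8, 0.7, 0.6, 0.5),
              cx = c(0.2, 0.35, 0.5, 0.65, 0.8),
              cy = c(0.2, 0.35, 0.5, 0.65, 0.8),
              w = rep(0.1, 5), h = rep(0.1, 5))
  # ranked TP/FP pattern: TP FP TP FP TP
  # recall:    1/3 1/3 2/3 2/3 1
  # precision:  1  1/2 2/3 1/2 3/5
  # all-points envelope: 1 on (0,1/3], 2/3 on (1/3,2/3], 3/5 on (2/3,1]
  # AP = (1/3)(1) + (1/3)(2/3) + (1/3)(3/5) = 34/45
  expect_equal(average_precision(d, g, 0.5, class = 0L), 34 / 45, tolerance = 1e-12)
  # 101-point interpolation of the same envelope
  ap101 <- average_precision(d, g, 0.5, class = 0L, interpolation = "101")
  rq <- seq(0, 1, length.out = 101)
  env <- ifelse(rq <= 1 / 3, 1, ifelse(rq <= 2 / 3, 2 / 3, 3 / 5))
  expect_equal(ap101, mean(env), tolerance = 1e-12)
})

test_that("duplicating an already-matched detection never increases AP", {
  set.seed(61)
  for (trial in 1:5) {
    ng <- sample(2:5, 1)
    g <- gt_df(cx = runif(ng, 0.2, 0.8), cy = runif(ng, 0.2, 0.8),
               w = runif(ng, 0.05, 0.15), h = runif(ng, 0.05, 0.15))
    nd <- sample(2:6, 1)
    pick <- sample(ng, nd, replace = TRUE)
    d <- det_df(conf = runif(nd, 0.3, 1),
                cx = g$cx[pick] + rnorm(nd, 0, 0.01),
                cy = g$cy[pick] + rnorm(nd, 0, 0.01),
                w = g$w[pick], h = g$h[pick])
    ap0 <- average_precision(d, g, 0.5)
    dup <- d[which.max(d$conf), ]
    dup$conf <- dup$conf * 0.99
    ap1 <- average_precision(rbind(d, dup), g, 0.5)
    expect_lte(ap1, ap0 + 1e-12)
  }
})

test_that("mAP is invariant to image ordering and mAP50 >= mAP50-95", {
  set.seed(62)
  mk <- function(img, n) {
    cx <- runif(n, 0.2, 0.8); cy <- runif(n, 0.2, 0.8)
    w <- runif(n, 0.05, 0.2); h <- runif(n, 0.05, 0.2)
    list(g = gt_df(cx, cy, w, h, image = img),
         d = det_df(runif(n), cx + rnorm(n, 0, 0.02), cy + rnorm(n, 0, 0.02),
                    w * runif(n, 0.8, 1.2), h * runif(n, 0.8, 1.2), image = img))
  }
  parts <- lapply(1:3, function(i) mk(i, 4))
  g <- do.call(rbind, lapply(parts, `[[`, "g"))
  d <- do.call(rbind, lapply(parts, `[[`, "d"))
  perm <- sample(nrow(d)); permg <- sample(nrow(g))
  i50 <- mean_average_precision(d, g, 0.5)
  expect_equal(mean_average_precision(d[perm, ], g[permg, ], 0.5), i50,
               tolerance = 1e-12)
  i5095 <- mean_average_precision(d, g, seq(0.5, 0.95, 0.05))
  expect_gte(i50 + 1e-12, i5095)
  expect_true(i50 >= 0 && i50 <= 1 && i5095 >= 0 && i5095 <= 1)
})
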