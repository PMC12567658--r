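# Full detector assembly at nano scale: stem + staged backbone (with taps at
# strides 4/8/16/32), spatial-pyramid pooling, an attention stage, a fusion
# neck and three decoupled detect heads.

m_backbone <- function(use_merca = FALSE, use_dhtst = FALSE) {
  stage <- function(c1, c2, c3k, e) {
    if (use_merca) merca(c1, c2) else m_c3k2(c1, c2, 1L, c3k = c3k, e = e)
  }
  new_module("m_backbone", children = list(
    l0 = m_conv(3L, 16L, 3L, stride = 2L),
    l1 = m_conv(16L, 32L, 3L, stride = 2L),
    l2 = stage(32L, 64L, FALSE, 0.25),
    l3 = m_conv(64L, 64L, 3L, stride = 2L),
    l4 = stage(64L, 128L, FALSE, 0.25),
    l5 = m_conv(128L, 128L, 3L, stride = 2L),
    l6 = stage(128L, 128L, TRUE, 0.5),
    l7 = m_conv(128L, 256L, 3L, stride = 2L),
    l8 = stage(256L, 256L, TRUE, 0.5),
    l9 = m_sppf(256L, 256L, 5L),
    l10 = if (use_dhtst) dhtst(256L) else m_c2psa(256L)))
}

mod_forward.m_backbone <- function(m, x, ...) {
  ch <- m$children
  x <- mod_forward(ch$l1, mod_forward(ch$l0, x))
  p2 <- mod_forward(ch$l2, x)
  p3 <- mod_forward(ch$l4, mod_forward(ch$l3, p2))
  p4 <- mod_forward(ch$l6, mod_forward(ch$l5, p3))
  p5 <- mod_forward(ch$l10, mod_forward(ch$l9, mod_forward(ch$l8, mod_forward(ch$l7, p4))))
  list(p2 = p2, p3 = p3, p4 = p4, p5 = p5)
}

mod_trace.m_backbone <- function(m, shape) {
  ch <- m$children
  macs <- 0
  s <- shape
  taps <- list()
  for (nm in c("l0", "l1", "l2", "l3", "l4", "l5", "l6", "l7", "l8", "l9", "l10")) {
    tr <- mod_trace(ch[[nm]], s)
    macs <- macs + tr$macs
    s <- tr$shape
    if (nm == "l2") taps$p2 <- s
    if (nm == "l4") taps$p3 <- s
    if (nm == "l6") taps$p4 <- s
    if (nm == "l10") taps$p5 <- s
  }
  list(shape = taps, macs = macs)
}

#' Build a detector graph
#'
#' Assembles the nano-scale one-stage detector. `variant` selects which of the
#' three lightweight replacements are active: the full improved model swaps
#' the backbone CSP stages for MERCA, the attention stage for DHTST, and the
#' path-aggregation neck for the weighted bidirectional neck with P2
#' injection; ablation variants toggle subsets, and the placement variants
#' move MERCA into the neck instead.
#'
#' @param variant one of `"baseline"`, `"lmtb"`, `"merca-backbone"`,
#'   `"merca-neck"`, `"merca-all"`, `"dhtst"`, `"bifpn"`, `"merca+dhtst"`,
#'   `"merca+bifpn"`, `"dhtst+bifpn"`.
#' @param scale model scale preset; only `"n"` (nano) is defined.
#' @param nc number of object classes (1 for the single tea-bud class).
#' @param seed optional RNG seed fixing the weight initialisation.
#' @return an object of class `lmtb_detector`.
#' @export
build_detector <- function(variant = "lmtb", scale = "n", nc = 1L, seed = NULL) {
  if (!identical(scale, "n"))
    stop("unknown scale preset: ", scale, call. = FALSE)
  variants <- c("baseline", "lmtb", "merca-backbone", "merca-neck", "merca-all",
                "dhtst", "bifpn", "merca+dhtst", "merca+bifpn", "dhtst+bifpn")
  if (!variant %in% variants)
    stop("unknown variant: ", variant, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  merca_bb <- variant %in% c("lmtb", "merca-backbone", "merca-all",
                             "merca+dhtst", "merca+bifpn")
  merca_nk <- variant %in% c("merca-neck", "merca-all")
  use_dhtst <- variant %in% c("lmtb", "dhtst", "merca+dhtst", "dhtst+bifpn")
  use_bifpn <- variant %in% c("lmtb", "bifpn", "merca+bifpn", "dhtst+bifpn")
  backbone <- m_backbone(use_merca = merca_bb, use_dhtst = use_dhtst)
  neck <- if (use_bifpn) bifpn() else if (merca_nk) m_pafpn_merca() else m_pafpn()
  head_ch <- if (use_bifpn) c(64L, 64L, 64L) else c(64L, 128L, 256L)
  g <- new_module("m_detector",
                  children = list(backbone = backbone, neck = neck,
                                  head = m_detect(head_ch, nc = nc)),
                  variant = variant, scale = scale, nc = nc,
                  strides = c(8L, 16L, 32L))
  class(g) <- c("lmtb_detector", class(g))
  g
}

#' @rdname build_detector
#' @export
build_baseline <- function(scale = "n", nc = 1L, seed = NULL) {
  build_detector("baseline", scale, nc, seed)
}

#' @rdname build_detector
#' @export
build_lmtb <- function(scale = "n", nc = 1L, seed = NULL) {
  build_detector("lmtb", scale, nc, seed)
}

mod_forward.m_detector <- function(m, x, ...) {
  levels <- mod_forward(m$children$backbone, x)
  neck_out <- if (inherits(m$children$neck, "m_bifpn")) {
    mod_forward(m$children$neck, levels)
  } else {
    mod_forward(m$children$neck, levels[c("p3", "p4", "p5")])
  }
  mod_forward(m$children$head, neck_out)
}

mod_trace.m_detector <- function(m, shape) {
  tb <- mod_trace(m$children$backbone, shape)
  tn <- if (inherits(m$children$neck, "m_bifpn")) {
    mod_trace(m$children$neck, tb$shape)
  } else {
    mod_trace(m$children$neck, tb$shape[c("p3", "p4", "p5")])
  }
  th <- mod_trace(m$children$head, tn$shape)
  list(shape = tn$shape, macs = tb$macs + tn$macs + th$macs,
       by = c(backbone = tb$macs, neck = tn$macs, head = th$macs))
}

#' Forward pass of a detector on one image
#'
#' @param g detector from [build_detector()].
#' @param img numeric (H, W, 3) array in `[0, 1]`; H and W must be multiples
#'   of 32.
#' @param grad keep the autodiff tape (needed for training)?
#' @return list with one element per pyramid level (strides 8/16/32), each
#'   holding raw `box` (H/s, W/s, 64) and `cls` (H/s, W/s, nc) maps.
#' @export
detector_forward <- function(g, img, grad = FALSE) {
  stopifnot(inherits(g, "lmtb_detector"))
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L || d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input must be (H, W, 3) with H, W multiples of 32", call. = FALSE)
  x <- tensor(img)
  out <- if (grad) mod_forward(g, x) else with_no_grad(mod_forward(g, x))
  if (grad) out else lapply(out, function(l) list(box = l$box$v, cls = l$cls$v))
}
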