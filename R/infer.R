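# Inference plumbing: distribution-focal box decoding and non-maximum
# suppression over the raw head maps. Decoding is fixed arithmetic (softmax
# expectation over the 16 distance bins), not a trainable layer.

softmax_mat <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# raw level output -> data frame of candidate boxes (normalised cxcywh)
decode_level <- function(box_map, cls_map, stride, img_hw, conf_t, reg_max = 16L) {
  d <- dim(box_map)
  H <- d[1]; W <- d[2]
  n <- H * W
  nc <- dim(cls_map)[3]
  bm <- matrix(box_map, n, 4L * reg_max)
  dist <- matrix(0, n, 4)
  bins <- 0:(reg_max - 1L)
  for (s in 1:4) {
    pr <- softmax_mat(bm[, (s - 1L) * reg_max + seq_len(reg_max), drop = FALSE])
    dist[, s] <- pr %*% bins
  }
  conf <- 1 / (1 + exp(-matrix(cls_map, n, nc)))
  best <- max.col(conf, ties.method = "first")
  bc <- conf[cbind(seq_len(n), best)]
  keep <- bc >= conf_t
  if (!any(keep)) {
    return(data.frame(class = integer(0), conf = numeric(0), cx = numeric(0),
                      cy = numeric(0), w = numeric(0), h = numeric(0)))
  }
  idx <- which(keep)
  rr <- ((idx - 1L) %% H) + 1L   # row (y cell)
  cc <- ((idx - 1L) %/% H) + 1L  # col (x cell)
  ax <- cc - 0.5; ay <- rr - 0.5
  x1 <- (ax - dist[idx, 1]) * stride; y1 <- (ay - dist[idx, 2]) * stride
  x2 <- (ax + dist[idx, 3]) * stride; y2 <- (ay + dist[idx, 4]) * stride
  data.frame(class = best[idx] - 1L, conf = bc[idx],
             cx = (x1 + x2) / 2 / img_hw[2], cy = (y1 + y2) / 2 / img_hw[1],
             w = (x2 - x1) / img_hw[2], h = (y2 - y1) / img_hw[1])
}

nms_greedy <- function(df, iou_t) {
  if (nrow(df) <= 1L) return(df)
  out <- NULL
  for (cl in unique(df$class)) {
    d <- df[df$class == cl, , drop = FALSE]
    d <- d[order(-d$conf), , drop = FALSE]
    keep <- logical(nrow(d))
    alive <- rep(TRUE, nrow(d))
    for (i in seq_len(nrow(d))) {
      if (!alive[i]) next
      keep[i] <- TRUE
      if (i < nrow(d)) {
        later <- (i + 1L):nrow(d)
        iou <- box_iou(as.matrix(d[i, c("cx", "cy", "w", "h")]),
                       as.matrix(d[later, c("cx", "cy", "w", "h")]))
        alive[later][iou[1, ] > iou_t] <- FALSE
      }
    }
    out <- rbind(out, d[keep, , drop = FALSE])
  }
  out[order(-out$conf), , drop = FALSE]
}

#' Decode raw detector output into detections
#'
#' Applies the distribution-focal expectation to the box bins, sigmoid to the
#' class logits, confidence filtering, and greedy per-class non-maximum
#' suppression.
#'
#' @param raw output of [detector_forward()] (with `grad = FALSE`).
#' @param img_hw input image (height, width) in pixels (one value = square).
#' @param conf confidence threshold (default 0.25).
#' @param iou NMS IoU threshold (default 0.45).
#' @param strides pyramid strides of the raw maps.
#' @return data frame `class, conf, cx, cy, w, h` (normalised boxes).
#' @export
decode_detections <- function(raw, img_hw, conf = 0.25, iou = 0.45,
                              strides = c(8L, 16L, 32L)) {
  if (length(img_hw) == 1L) img_hw <- c(img_hw, img_hw)
  dets <- do.call(rbind, lapply(seq_along(raw), function(i) {
    decode_level(raw[[i]]$box, raw[[i]]$cls, strides[i], img_hw, conf)
  }))
  if (is.null(dets) || nrow(dets) == 0L) return(dets)
  nms_greedy(dets, iou)
}
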