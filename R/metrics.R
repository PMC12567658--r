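# Detection metrics: IoU matching, precision/recall, and mean average
# precision with all-points (default) or 101-point interpolation.
#
# Detections and ground truths are data frames with one row per box:
#   image (id), class (integer), cx, cy, w, h  (normalised to [0, 1]),
# and detections additionally carry `conf` in [0, 1].

check_boxes <- function(df, what = "boxes") {
  need <- c("cx", "cy", "w", "h")
  if (!all(need %in% names(df)))
    stop(what, " need columns cx, cy, w, h", call. = FALSE)
  b <- as.matrix(df[, need])
  if (nrow(df) && (!all(is.finite(b)) || any(df$w <= 0) || any(df$h <= 0)))
    stop("malformed ", what, ": non-finite or non-positive extents", call. = FALSE)
  invisible(df)
}

#' Intersection over union of axis-aligned boxes
#'
#' @param a,b matrices (or vectors) of boxes in `(cx, cy, w, h)` form.
#' @return `nrow(a)` x `nrow(b)` IoU matrix.
#' @export
box_iou <- function(a, b) {
  a <- matrix(a, ncol = 4)
  b <- matrix(b, ncol = 4)
  ax1 <- a[, 1] - a[, 3] / 2; ax2 <- a[, 1] + a[, 3] / 2
  ay1 <- a[, 2] - a[, 4] / 2; ay2 <- a[, 2] + a[, 4] / 2
  bx1 <- b[, 1] - b[, 3] / 2; bx2 <- b[, 1] + b[, 3] / 2
  by1 <- b[, 2] - b[, 4] / 2; by2 <- b[, 2] + b[, 4] / 2
  iw <- pmax(outer(ax2, bx2, pmin) - outer(ax1, bx1, pmax), 0)
  ih <- pmax(outer(ay2, by2, pmin) - outer(ay1, by1, pmax), 0)
  inter <- iw * ih
  union <- outer(a[, 3] * a[, 4], b[, 3] * b[, 4], "+") - inter
  ifelse(union > 0, inter / union, 0)
}

# greedy one-to-one matching by descending confidence within one image+class;
# returns logical TP flag per detection (in the sorted order given)
greedy_match <- function(det_boxes, gt_boxes, iou_t) {
  nd <- nrow(det_boxes)
  ng <- nrow(gt_boxes)
  tp <- logical(nd)
  if (nd == 0L || ng == 0L) return(tp)
  iou <- box_iou(det_boxes, gt_boxes)
  used <- logical(ng)
  for (i in seq_len(nd)) {
    cand <- which(!used & iou[i, ] >= iou_t)
    if (length(cand)) {
      j <- cand[which.max(iou[i, cand])]
      used[j] <- TRUE
      tp[i] <- TRUE
    }
  }
  tp
}

#' Match detections against ground truth at one IoU threshold
#'
#' Detections are sorted by descending confidence; each matches the
#' highest-IoU unmatched ground-truth box of the same class in the same image
#' with IoU at or above the threshold (greedy one-to-one assignment).
#'
#' @param dets detection data frame (`image`, `class`, `conf`, `cx,cy,w,h`).
#' @param gts ground-truth data frame (`image`, `class`, `cx,cy,w,h`).
#' @param iou_t IoU threshold in (0, 1).
#' @return list with counts `TP`, `FP`, `FN`.
#' @export
match_detections <- function(dets, gts, iou_t = 0.5) {
  if (iou_t <= 0 || iou_t >= 1) stop("iou_t must be in (0, 1)", call. = FALSE)
  check_boxes(dets, "detections")
  check_boxes(gts, "ground truths")
  tp <- 0L
  for (img in unique(c(dets$image, gts$image))) {
    for (cl in unique(c(dets$class, gts$class))) {
      d <- dets[dets$image == img & dets$class == cl, , drop = FALSE]
      g <- gts[gts$image == img & gts$class == cl, , drop = FALSE]
      if (nrow(d)) d <- d[order(-d$conf), , drop = FALSE]
      tp <- tp + sum(greedy_match(as.matrix(d[, c("cx", "cy", "w", "h")]),
                                  as.matrix(g[, c("cx", "cy", "w", "h")]), iou_t))
    }
  }
  list(TP = tp, FP = nrow(dets) - tp, FN = nrow(gts) - tp)
}

#' Precision and recall from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`; the degenerate `0/0` case is
#' defined as 0.
#'
#' @param TP,FP,FN nonnegative counts (or a list from [match_detections()]
#'   passed as `TP`).
#' @return list with `P` and `R`.
#' @export
precision_recall <- function(TP, FP = NULL, FN = NULL) {
  if (is.list(TP)) { FP <- TP$FP; FN <- TP$FN; TP <- TP$TP }
  if (any(c(TP, FP, FN) < 0)) stop("counts must be nonnegative", call. = FALSE)
  list(P = if (TP + FP > 0) TP / (TP + FP) else 0,
       R = if (TP + FN > 0) TP / (TP + FN) else 0)
}

# per-class PR curve points over the whole image set
pr_curve <- function(dets, gts, iou_t, cl) {
  d <- dets[dets$class == cl, , drop = FALSE]
  n_gt <- sum(gts$class == cl)
  if (nrow(d) == 0L || n_gt == 0L) {
    return(list(recall = numeric(0), precision = numeric(0), n_gt = n_gt))
  }
  d <- d[order(-d$conf), , drop = FALSE]
  tp <- logical(nrow(d))
  for (img in unique(d$image)) {
    sel <- d$image == img
    g <- gts[gts$image == img & gts$class == cl, , drop = FALSE]
    tp[sel] <- greedy_match(as.matrix(d[sel, c("cx", "cy", "w", "h")]),
                            as.matrix(g[, c("cx", "cy", "w", "h")]), iou_t)
  }
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  list(recall = ctp / n_gt, precision = ctp / (ctp + cfp), n_gt = n_gt)
}

ap_from_curve <- function(recall, precision, interpolation = "all") {
  if (!length(recall)) return(0)
  r <- c(0, recall)
  p <- c(1, precision)
  # precision envelope: p(r) := max precision at recall >= r
  p <- rev(cummax(rev(p)))
  if (interpolation == "all") {
    sum(diff(r) * p[-1])
  } else {
    rq <- seq(0, 1, length.out = 101L)
    pe <- vapply(rq, function(q) {
      i <- which(r >= q)
      if (length(i)) max(p[i]) else 0
    }, numeric(1))
    mean(pe)
  }
}

#' Average precision for one class at one IoU threshold
#'
#' Area under the interpolated precision-recall curve; `interpolation =
#' "all"` integrates the exact precision envelope over recall (the default),
#' `"101"` averages the envelope at 101 evenly spaced recall points.
#'
#' @inheritParams match_detections
#' @param class class id.
#' @param interpolation `"all"` or `"101"`.
#' @export
average_precision <- function(dets, gts, iou_t = 0.5, class = 0L,
                              interpolation = c("all", "101")) {
  interpolation <- match.arg(interpolation)
  check_boxes(dets, "detections")
  check_boxes(gts, "ground truths")
  cv <- pr_curve(dets, gts, iou_t, class)
  ap_from_curve(cv$recall, cv$precision, interpolation)
}

#' Mean average precision over classes and IoU thresholds
#'
#' Per-class average precision is averaged over every class present in the
#' ground truth or detections (a class with detections but no ground truth
#' scores 0), then over the IoU thresholds: `iou_list = 0.5` gives mAP50,
#' `seq(0.5, 0.95, 0.05)` gives mAP50-95.
#'
#' @inheritParams average_precision
#' @param iou_list numeric vector of IoU thresholds.
#' @export
mean_average_precision <- function(dets, gts, iou_list = 0.5,
                                   interpolation = c("all", "101")) {
  interpolation <- match.arg(interpolation)
  check_boxes(dets, "detections")
  check_boxes(gts, "ground truths")
  classes <- sort(unique(c(dets$class, gts$class)))
  if (!length(classes)) stop("no classes present", call. = FALSE)
  mean(vapply(iou_list, function(t) {
    mean(vapply(classes, function(cl) {
      average_precision(dets, gts, t, cl, interpolation)
    }, numeric(1)))
  }, numeric(1)))
}
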