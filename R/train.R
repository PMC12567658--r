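# Simplified dense training objective and SGD smoke loop. This is not the
# full detection loss of a production training run (no task-aligned
# assignment, no CIoU); it is a dense per-cell objective whose only job is to
# exercise every parameter group end to end on CPU and demonstrate
# tiny-set overfitting: a cell-wise MSE between the sigmoid class map and a
# centre-cell objectness target, plus an MSE on the distribution-focal
# distance expectations at positive cells (both branches of every head
# receive gradient).

#' Dense per-level training targets for one image
#'
#' @param anns normalised annotations (`class, cx, cy, w, h`).
#' @param hw image (height, width) in pixels (one value = square).
#' @param strides pyramid strides.
#' @param reg_max number of distance bins of the box branch.
#' @return per level: `obj` (H/s x W/s objectness matrix), `pos` (linear cell
#'   indices of box centres) and `ltrb` (|pos| x 4 matrix of centre-to-edge
#'   distances in stride units, scaled to `[0, 1]` by `reg_max`).
#' @export
dense_targets <- function(anns, hw, strides = c(8L, 16L, 32L), reg_max = 16L) {
  if (length(hw) == 1L) hw <- c(hw, hw)
  lapply(strides, function(s) {
    H <- hw[1] %/% s; W <- hw[2] %/% s
    obj <- matrix(0, H, W)
    pos <- integer(0)
    ltrb <- matrix(0, 0, 4)
    if (nrow(anns)) {
      cxf <- anns$cx * hw[2] / s; cyf <- anns$cy * hw[1] / s
      wf <- anns$w * hw[2] / s; hf <- anns$h * hw[1] / s
      cc <- pmin(pmax(ceiling(cxf), 1L), W)
      rr <- pmin(pmax(ceiling(cyf), 1L), H)
      for (i in seq_len(nrow(anns))) {
        obj[rr[i], cc[i]] <- 1
        pos <- c(pos, rr[i] + H * (cc[i] - 1L))
        ax <- cc[i] - 0.5; ay <- rr[i] - 0.5
        d <- c(ax - (cxf[i] - wf[i] / 2), ay - (cyf[i] - hf[i] / 2),
               (cxf[i] + wf[i] / 2) - ax, (cyf[i] + hf[i] / 2) - ay)
        ltrb <- rbind(ltrb, pmin(pmax(d, 0), reg_max - 1) / reg_max)
      }
      dup <- !duplicated(pos)
      pos <- pos[dup]
      ltrb <- ltrb[dup, , drop = FALSE]
    }
    list(obj = obj, pos = pos, ltrb = ltrb)
  })
}

op_select_rows <- function(a, idx) {
  tns_op(a$v[idx, , drop = FALSE], list(a), function(g) {
    gv <- matrix(0, nrow(a$v), ncol(a$v))
    gv[idx, ] <- gv[idx, ] + g
    list(gv)
  })
}

#' Dense detection loss on one image (keeps the autodiff tape)
#'
#' @param g detector from [build_detector()].
#' @param img (H, W, 3) array.
#' @param anns annotations for the image.
#' @param box_weight weight of the box-distance term.
#' @return scalar loss tensor; call `backward()` upstream or use
#'   [train_smoke()].
#' @keywords internal
detection_loss_t <- function(g, img, anns, box_weight = 1) {
  hw <- dim(img)[1:2]
  raw <- detector_forward(g, img, grad = TRUE)
  tg <- dense_targets(anns, hw, strides = c(8L, 16L, 32L))
  total <- NULL
  for (i in seq_along(raw)) {
    cls <- raw[[i]]$cls
    d <- dim(cls$v)
    err <- op_sub(op_sigmoid(cls), tensor(array(tg[[i]]$obj, dim = d)))
    lv <- op_mean(op_square(err))
    if (length(tg[[i]]$pos)) {
      bm <- op_tokens(raw[[i]]$box)  # n x 64
      reg <- 16L
      bins <- matrix(0:(reg - 1L) / reg, reg, 1)
      preds <- vector("list", 4L)
      for (s in 1:4) {
        pr <- softmax_rows(op_slice_cols(bm, (s - 1L) * reg + 1L, s * reg))
        preds[[s]] <- op_matmul(pr, tensor(bins))
      }
      pred <- cbind_cols(preds)  # n x 4 expectations in [0,1)
      sel <- op_select_rows(pred, tg[[i]]$pos)
      berr <- op_sub(sel, tensor(tg[[i]]$ltrb))
      lv <- op_add(lv, op_smul(op_mean(op_square(berr)), box_weight))
    }
    total <- if (is.null(total)) lv else op_add(total, lv)
  }
  total
}

#' Dense detection loss (value only)
#'
#' @inheritParams detection_loss_t
#' @return numeric scalar.
#' @export
detection_loss <- function(g, img, anns, box_weight = 1) {
  with_no_grad(detection_loss_t(g, img, anns, box_weight))$v
}

#' CPU training smoke run on synthetic scenes
#'
#' Generates a handful of synthetic tea scenes, then runs plain
#' SGD-with-momentum steps of the dense loss, one image per step in rotation.
#' Verifies end-to-end trainability: the loss trajectory and a record of
#' which parameters ever received a nonzero gradient are returned.
#'
#' @param model detector to train (default: freshly built improved model).
#' @param n_scenes number of scenes.
#' @param steps SGD steps.
#' @param hw square image size in pixels (multiple of 32).
#' @param lr learning rate.
#' @param momentum heavy-ball momentum.
#' @param weight_decay L2 coefficient.
#' @param seed seed for scenes and initialisation.
#' @return list: `losses` (per-step values), `loss0` / `loss_end` (mean loss
#'   over all scenes before and after training), `grad_seen` (named logical
#'   per parameter), `model`.
#' @export
train_smoke <- function(model = NULL, n_scenes = 8L, steps = 200L, hw = 320L,
                        lr = 0.2, momentum = 0.9, weight_decay = 1e-5,
                        seed = 7L) {
  scenes <- lapply(seq_len(n_scenes), function(i) {
    generate_scene(scene_spec(size = hw, n_targets = c(6L, 14L),
                              base_size = 0.035, seed = seed * 1000L + i))
  })
  if (is.null(model)) model <- build_lmtb(seed = seed)
  params <- mod_params(model)
  vel <- lapply(params, function(p) 0 * p$v)
  grad_seen <- stats::setNames(rep(FALSE, length(params)), names(params))
  mean_loss <- function() {
    mean(vapply(scenes, function(s) {
      detection_loss(model, s$image, s$annotations)
    }, numeric(1)))
  }
  loss0 <- mean_loss()
  losses <- numeric(steps + 1L)
  losses[1L] <- detection_loss(model, scenes[[1L]]$image, scenes[[1L]]$annotations)
  for (step in seq_len(steps)) {
    sc <- scenes[[(step - 1L) %% n_scenes + 1L]]
    zero_grads(params)
    loss <- detection_loss_t(model, sc$image, sc$annotations)
    backward(loss)
    for (i in seq_along(params)) {
      p <- params[[i]]
      if (is.null(p$grad)) next
      if (!grad_seen[i] && any(p$grad != 0)) grad_seen[i] <- TRUE
      g <- p$grad + weight_decay * p$v
      vel[[i]] <- momentum * vel[[i]] - lr * g
      p$v <- p$v + vel[[i]]
    }
    losses[step + 1L] <- loss$v
  }
  list(losses = losses, loss0 = loss0, loss_end = mean_loss(),
       grad_seen = grad_seen, model = model)
}
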