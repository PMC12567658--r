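# Synthetic tea-scene generator. Emulates the study regime of the field data:
# densely clustered, mutually occluding, low-contrast bud-like targets on a
# textured green background, spanning a wide size range (tightly wrapped tips
# a few millimetres across against young leaves up to ~2 cm, i.e. roughly a
# 5x linear scale spread). Not a photorealistic plant renderer: targets are
# rotated soft-edged ellipses whose luminance sits a controlled distance from
# the background.

#' Scene specification
#'
#' @param size image side length in pixels.
#' @param n_targets number of bud targets (a single count or a range to
#'   sample from).
#' @param scale_spread ratio of largest to smallest target minor axis
#'   (default 5, the tip-to-leaf regime); the first two targets are pinned to
#'   the extremes so every scene spans the full range.
#' @param base_size minor axis of the smallest target, as a fraction of the
#'   image side.
#' @param contrast mean foreground/background luminance distance (low values
#'   emulate the bud-vs-canopy camouflage).
#' @param cluster_tightness spread of targets around cluster centres, as a
#'   fraction of the image side (smaller = denser, more occlusion).
#' @param targets_per_cluster average cluster occupancy.
#' @param illumination amplitude of a smooth illumination gradient.
#' @param seed RNG seed; fixes all randomness of [generate_scene()].
#' @return an `lmtb_scene_spec` list.
#' @export
scene_spec <- function(size = 640L, n_targets = c(12L, 30L), scale_spread = 5,
                       base_size = 0.022, contrast = 0.10,
                       cluster_tightness = 0.06, targets_per_cluster = 6,
                       illumination = 0.08, seed = 0L) {
  if (scale_spread < 1) stop("scale_spread must be >= 1", call. = FALSE)
  if (any(n_targets < 0)) stop("target count must be nonnegative", call. = FALSE)
  structure(list(size = as.integer(size), n_targets = n_targets,
                 scale_spread = scale_spread, base_size = base_size,
                 contrast = contrast, cluster_tightness = cluster_tightness,
                 targets_per_cluster = targets_per_cluster,
                 illumination = illumination, seed = as.integer(seed)),
            class = "lmtb_scene_spec")
}

# smooth value-noise field: coarse uniform grid, bilinearly upsampled
noise_field <- function(size, cells) {
  g <- matrix(runif(cells * cells, -1, 1), cells, cells)
  A <- bilinear_matrix(cells, size)
  A %*% g %*% t(A)
}

#' Generate one synthetic tea scene
#'
#' Renders elongated low-contrast bud-like blobs on a textured green
#' background and returns tight normalised boxes. Deterministic given
#' `spec$seed`.
#'
#' @param spec from [scene_spec()].
#' @return list with `image` (size x size x 3 array in `[0,1]`) and
#'   `annotations` (data frame `class, cx, cy, w, h`).
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "lmtb_scene_spec"))
  set.seed(spec$seed)
  S <- spec$size
  n <- if (length(spec$n_targets) > 1L) {
    sample(spec$n_targets[1]:spec$n_targets[2], 1L)
  } else as.integer(spec$n_targets)

  # background: green hue band, low-frequency texture + illumination gradient
  tex <- 0.5 * noise_field(S, 9L) + 0.3 * noise_field(S, 31L)
  ang <- runif(1, 0, 2 * pi)
  gx <- matrix(seq(-0.5, 0.5, length.out = S), S, S, byrow = TRUE)
  gy <- matrix(seq(-0.5, 0.5, length.out = S), S, S)
  illum <- spec$illumination * (cos(ang) * gx + sin(ang) * gy)
  lum <- 0.42 + 0.06 * tex + illum
  img <- array(0, dim = c(S, S, 3))
  img[, , 1] <- lum * 0.55
  img[, , 2] <- lum * 1.15
  img[, , 3] <- lum * 0.45

  if (n == 0L) {
    return(list(image = pmin(pmax(img, 0), 1),
                annotations = data.frame(class = integer(0), cx = numeric(0),
                                         cy = numeric(0), w = numeric(0),
                                         h = numeric(0))))
  }

  smin <- spec$base_size * S
  smax <- smin * spec$scale_spread
  n_cl <- max(1L, ceiling(n / spec$targets_per_cluster))
  cl_x <- runif(n_cl, 0.15 * S, 0.85 * S)
  cl_y <- runif(n_cl, 0.15 * S, 0.85 * S)

  anns <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                     w = numeric(0), h = numeric(0))
  for (i in seq_len(n)) {
    # pin the first two targets to the size extremes (placed fully inside)
    minor <- if (i == 1L) smin else if (i == 2L) smax
      else exp(runif(1, log(smin), log(smax)))
    aspect <- runif(1, 2.2, 3.6)
    a <- minor * aspect / 2    # semi-major
    b <- minor / 2             # semi-minor
    th <- runif(1, 0, pi)
    ex <- sqrt((a * cos(th))^2 + (b * sin(th))^2)  # tight half extents
    ey <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
    placed <- FALSE
    for (attempt in 1:25) {
      k <- sample.int(n_cl, 1L)
      cx <- cl_x[k] + rnorm(1, 0, spec$cluster_tightness * S)
      cy <- cl_y[k] + rnorm(1, 0, spec$cluster_tightness * S)
      if (i <= 2L) {  # extremes must survive unclipped
        cx <- min(max(cx, ex + 2), S - ex - 2)
        cy <- min(max(cy, ey + 2), S - ey - 2)
      }
      if (cx + ex > 1 && cx - ex < S && cy + ey > 1 && cy - ey < S) {
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place target ", i, " after 25 attempts; ",
                      "reduce target count or size", call. = FALSE)

    # render the rotated soft-edged ellipse into a local patch
    x1 <- max(1L, floor(cx - ex)); x2 <- min(S, ceiling(cx + ex))
    y1 <- max(1L, floor(cy - ey)); y2 <- min(S, ceiling(cy + ey))
    px <- seq(x1, x2); py <- seq(y1, y2)
    dx <- outer(rep(1, length(py)), px - cx)
    dy <- outer(py - cy, rep(1, length(px)))
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    r2 <- u * u + v * v
    alpha <- pmin(pmax((1 - r2) / 0.25, 0), 1)  # soft rim
    dl <- spec$contrast * runif(1, 0.7, 1.3)    # per-target luminance offset
    tint <- c(0.52, 1.22, 0.40) * (0.42 + dl)
    for (ch in 1:3) {
      img[py, px, ch] <- img[py, px, ch] * (1 - alpha) + alpha * tint[ch]
    }

    bx1 <- max(cx - ex, 0); bx2 <- min(cx + ex, S)
    by1 <- max(cy - ey, 0); by2 <- min(cy + ey, S)
    if (bx2 - bx1 >= 1 && by2 - by1 >= 1) {
      anns <- rbind(anns, data.frame(class = 0L,
                                     cx = (bx1 + bx2) / 2 / S,
                                     cy = (by1 + by2) / 2 / S,
                                     w = (bx2 - bx1) / S,
                                     h = (by2 - by1) / S))
    }
  }
  list(image = pmin(pmax(img, 0), 1), annotations = anns)
}

#' Mosaic augmentation
#'
#' Combines four samples into one canvas as a 2x2 collage around a random
#' centre: each source keeps its native scale, anchored so its far corner
#' meets the centre point, and is cropped to its quadrant. Labels are
#' translated, clipped to the visible region, and dropped when the clipped
#' box falls below `min_side` pixels on either side.
#'
#' @param samples list of 4 lists with `image` and `annotations` (as returned
#'   by [generate_scene()]); all images must share one square size.
#' @param seed RNG seed for the centre draw.
#' @param min_side minimum surviving box side in pixels.
#' @return list with `image` and `annotations` on the same canvas size.
#' @export
mosaic_augment <- function(samples, seed = 0L, min_side = 3) {
  if (length(samples) != 4L) stop("mosaic needs exactly 4 samples", call. = FALSE)
  S <- dim(samples[[1]]$image)[1]
  for (s in samples) {
    if (!identical(dim(s$image)[1:2], c(S, S)))
      stop("all mosaic inputs must share one square size", call. = FALSE)
  }
  set.seed(seed)
  xc <- round(runif(1, 0.25, 0.75) * S)
  yc <- round(runif(1, 0.25, 0.75) * S)
  canvas <- array(0, dim = c(S, S, 3))
  anns <- NULL
  # quadrant rects (x1, y1, x2, y2) and source offsets (ox, oy):
  # canvas_coord = source_coord + offset
  quads <- list(list(r = c(1, 1, xc, yc), o = c(xc - S, yc - S)),
                list(r = c(xc + 1, 1, S, yc), o = c(xc, yc - S)),
                list(r = c(1, yc + 1, xc, S), o = c(xc - S, yc)),
                list(r = c(xc + 1, yc + 1, S, S), o = c(xc, yc)))
  for (q in seq_len(4L)) {
    rc <- quads[[q]]$r; of <- quads[[q]]$o
    if (rc[3] < rc[1] || rc[4] < rc[2]) next
    sx <- (rc[1]:rc[3]) - of[1]; sy <- (rc[2]:rc[4]) - of[2]
    canvas[rc[2]:rc[4], rc[1]:rc[3], ] <- samples[[q]]$image[sy, sx, , drop = FALSE]
    an <- samples[[q]]$annotations
    if (is.null(an) || nrow(an) == 0L) next
    # pixel corners in canvas coordinates
    x1 <- (an$cx - an$w / 2) * S + of[1]; x2 <- (an$cx + an$w / 2) * S + of[1]
    y1 <- (an$cy - an$h / 2) * S + of[2]; y2 <- (an$cy + an$h / 2) * S + of[2]
    # clip to the visible quadrant
    x1 <- pmax(x1, rc[1] - 1); x2 <- pmin(x2, rc[3])
    y1 <- pmax(y1, rc[2] - 1); y2 <- pmin(y2, rc[4])
    keep <- (x2 - x1) >= min_side & (y2 - y1) >= min_side
    if (any(keep)) {
      anns <- rbind(anns, data.frame(
        class = an$class[keep],
        cx = (x1 + x2)[keep] / 2 / S, cy = (y1 + y2)[keep] / 2 / S,
        w = (x2 - x1)[keep] / S, h = (y2 - y1)[keep] / S))
    }
  }
  if (is.null(anns)) {
    anns <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                       w = numeric(0), h = numeric(0))
  }
  list(image = canvas, annotations = anns)
}

#' Deterministic train/test/val split
#'
#' Shuffles with the seed, then assigns `floor(r_train * n)` items to train,
#' `floor(r_val * n)` to val, and the remainder to test -- the rounding that
#' reproduces the published 3062 = 2143 + 613 + 306 arithmetic at 7:2:1.
#'
#' @param items vector (or list) of items to split.
#' @param ratios train/test/val shares summing to 1.
#' @param seed shuffle seed.
#' @return list with `train`, `test`, `val`.
#' @export
split_dataset <- function(items, ratios = c(0.7, 0.2, 0.1), seed = 0L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be three shares summing to 1", call. = FALSE)
  n <- length(items)
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- floor(ratios[1] * n)
  n_val <- floor(ratios[3] * n)
  n_test <- n - n_train - n_val
  list(train = items[perm[seq_len(n_train)]],
       test = items[perm[n_train + seq_len(n_test)]],
       val = items[perm[n_train + n_test + seq_len(n_val)]])
}

# ---- YOLO TXT label IO ------------------------------------------------------

#' Write YOLO-format TXT labels
#'
#' One `class cx cy w h` line per box, space-separated, normalised floats.
#'
#' @param anns data frame `class, cx, cy, w, h`.
#' @param path output file.
#' @export
write_yolo_labels <- function(anns, path) {
  lines <- sprintf("%d %.10f %.10f %.10f %.10f",
                   as.integer(anns$class), anns$cx, anns$cy, anns$w, anns$h)
  writeLines(lines, path)
  invisible(path)
}

#' Read YOLO-format TXT labels
#'
#' @param path label file.
#' @return data frame `class, cx, cy, w, h`.
#' @export
read_yolo_labels <- function(path) {
  if (!file.exists(path)) stop("no such label file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  }
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(m) != 5L) stop("malformed YOLO label file: ", path, call. = FALSE)
  data.frame(class = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
             w = m[, 4], h = m[, 5])
}

#' Generate a synthetic dataset on disk
#'
#' Writes PNG images, YOLO TXT labels, a YAML manifest, and the 7:2:1 split.
#'
#' @param n number of scenes.
#' @param out_dir output directory (created).
#' @param spec base [scene_spec()]; scene `i` uses `spec$seed + i`.
#' @param ratios split shares passed to [split_dataset()].
#' @return the manifest list, invisibly.
#' @export
generate_dataset <- function(n, out_dir, spec = scene_spec(),
                             ratios = c(0.7, 0.2, 0.1)) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  stems <- sprintf("scene_%04d", seq_len(n))
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- spec$seed + i
    sc <- generate_scene(sp)
    png::writePNG(sc$image, file.path(out_dir, "images", paste0(stems[i], ".png")))
    write_yolo_labels(sc$annotations,
                      file.path(out_dir, "labels", paste0(stems[i], ".txt")))
  }
  split <- split_dataset(stems, ratios, seed = spec$seed)
  manifest <- list(n = n, size = spec$size, classes = list("tea bud"),
                   seed = spec$seed, split = split)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
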