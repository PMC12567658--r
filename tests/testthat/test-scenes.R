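# Synthetic scene generator, mosaic augmentation, dataset splitting, label IO.

test_that("scene generation is bit-identical under a fixed seed", {
  sp <- scene_spec(size = 160L, seed = 99L)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$annotations, b$annotations)
  # a different seed changes the scene
  c <- generate_scene(scene_spec(size = 160L, seed = 100L))
  expect_false(identical(a$image, c$image))
})

test_that("emitted boxes are valid normalised boxes with positive area", {
  for (seed in c(1, 2, 3)) {
    sc <- generate_scene(scene_spec(size = 192L, seed = seed))
    an <- sc$annotations
    expect_gt(nrow(an), 0)
    expect_true(all(an$w > 0 & an$h > 0))
    expect_true(all(an$cx - an$w / 2 >= -1e-9 & an$cx + an$w / 2 <= 1 + 1e-9))
    expect_true(all(an$cy - an$h / 2 >= -1e-9 & an$cy + an$h / 2 <= 1 + 1e-9))
    expect_true(all(sc$image >= 0 & sc$image <= 1))
  }
})

test_that("scenes span the configured multi-scale regime", {
  sc <- generate_scene(scene_spec(size = 320L, n_targets = 30L,
                                  scale_spread = 5, seed = 7L))
  an <- sc$annotations
  sides <- pmin(an$w, an$h)
  expect_gte(max(sides) / min(sides), 4)
})

test_that("mosaic of four centred-box samples yields one box per quadrant", {
  S <- 64L
  img <- array(0.5, dim = c(S, S, 3))
  an <- data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 0.25, h = 0.25)
  smp <- list(image = img, annotations = an)
  # seed chosen so the centre draw lands mid-canvas; boxes split across quadrants
  out <- mosaic_augment(list(smp, smp, smp, smp), seed = 33L)
  expect_identical(dim(out$image), dim(img))
  expect_equal(nrow(out$annotations), 4L)
  xc <- sort(unique(round(out$annotations$cx, 3)))
  yc <- sort(unique(round(out$annotations$cy, 3)))
  expect_length(xc, 2L)  # two distinct x positions -> left/right quadrants
  expect_length(yc, 2L)
  expect_error(mosaic_augment(list(smp, smp, smp), seed = 1L), "exactly 4")
})

test_that("mosaic only removes labels and keeps survivors inside the canvas", {
  set.seed(71)
  for (seed in 1:5) {
    smps <- lapply(1:4, function(i) {
      generate_scene(scene_spec(size = 96L, n_targets = c(4L, 8L),
                                seed = seed * 10L + i))
    })
    out <- mosaic_augment(smps, seed = seed)
    n_in <- sum(vapply(smps, function(s) nrow(s$annotations), numeric(1)))
    an <- out$annotations
    expect_lte(nrow(an), n_in)
    if (nrow(an)) {
      expect_true(all(an$cx - an$w / 2 >= -1e-9 & an$cx + an$w / 2 <= 1 + 1e-9))
      expect_true(all(an$cy - an$h / 2 >= -1e-9 & an$cy + an$h / 2 <= 1 + 1e-9))
    }
  }
})

test_that("mosaic labels agree with a corner-transform oracle", {
  set.seed(72)
  S <- 96L
  smps <- lapply(1:4, function(i) {
    generate_scene(scene_spec(size = S, n_targets = 6L, seed = 200L + i))
  })
  out <- mosaic_augment(smps, seed = 3L, min_side = 3)
  # oracle: recompute the centre, transform each source box's corners by the
  # quadrant offset, clip to the quadrant rectangle, keep those above min side
  set.seed(3L)
  xc <- round(runif(1, 0.25, 0.75) * S)
  yc <- round(runif(1, 0.25, 0.75) * S)
  offs <- list(c(xc - S, yc - S), c(xc, yc - S), c(xc - S, yc), c(xc, yc))
  rects <- list(c(0, 0, xc, yc), c(xc, 0, S, yc), c(0, yc, xc, S), c(xc, yc, S, S))
  oracle <- NULL
  for (q in 1:4) {
    an <- smps[[q]]$annotations
    for (r in seq_len(nrow(an))) {
      cs <- c(an$cx[r] - an$w[r] / 2, an$cy[r] - an$h[r] / 2,
              an$cx[r] + an$w[r] / 2, an$cy[r] + an$h[r] / 2) * S
      cs <- cs + offs[[q]][c(1, 2, 1, 2)]
      cs <- c(max(cs[1], rects[[q]][1]), max(cs[2], rects[[q]][2]),
              min(cs[3], rects[[q]][3]), min(cs[4], rects[[q]][4]))
      if (cs[3] - cs[1] >= 3 && cs[4] - cs[2] >= 3) {
        oracle <- rbind(oracle, data.frame(
          cx = (cs[1] + cs[3]) / 2 / S, cy = (cs[2] + cs[4]) / 2 / S,
          w = (cs[3] - cs[1]) / S, h = (cs[4] - cs[2]) / S))
      }
    }
  }
  expect_equal(nrow(out$annotations), nrow(oracle))
  iou <- box_iou(as.matrix(out$annotations[, c("cx", "cy", "w", "h")]),
                 as.matrix(oracle))
  expect_true(all(apply(iou, 1, max) >= 0.99))
})

test_that("the 7:2:1 split reproduces the published arithmetic", {
  sp <- split_dataset(seq_len(3062), seed = 1L)
  expect_identical(lengths(sp), c(train = 2143L, test = 613L, val = 306L))
  sp10 <- split_dataset(seq_len(10), seed = 1L)
  expect_identical(lengths(sp10), c(train = 7L, test = 2L, val = 1L))
  expect_error(split_dataset(1:10, ratios = c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("splits are disjoint, exhaustive and seed-deterministic", {
  set.seed(73)
  for (trial in 1:100) {
    n <- sample(3:500, 1)
    sp <- split_dataset(seq_len(n), seed = trial)
    all_items <- c(sp$train, sp$test, sp$val)
    expect_identical(sort(all_items), seq_len(n))
    expect_identical(anyDuplicated(all_items), 0L)
    sp2 <- split_dataset(seq_len(n), seed = trial)
    expect_identical(sp, sp2)
  }
})

test_that("YOLO label files round-trip to 1e-9", {
  set.seed(74)
  an <- data.frame(class = c(0L, 0L, 1L), cx = runif(3), cy = runif(3),
                   w = runif(3, 0.01, 0.3), h = runif(3, 0.01, 0.3))
  path <- tempfile(fileext = ".txt")
  write_yolo_labels(an, path)
  back <- read_yolo_labels(path)
  expect_equal(back$cx, an$cx, tolerance = 1e-9)
  expect_equal(back$cy, an$cy, tolerance = 1e-9)
  expect_equal(back$w, an$w, tolerance = 1e-9)
  expect_equal(back$h, an$h, tolerance = 1e-9)
  expect_identical(back$class, an$class)
  unlink(path)
})

test_that("generate_dataset writes images, labels, manifest and split", {
  out <- tempfile("scenes")
  man <- generate_dataset(10L, out, scene_spec(size = 96L, n_targets = c(3L, 6L),
                                               seed = 5L))
  expect_length(list.files(file.path(out, "images"), pattern = "\\.png$"), 10L)
  expect_length(list.files(file.path(out, "labels"), pattern = "\\.txt$"), 10L)
  man2 <- yaml::read_yaml(file.path(out, "manifest.yaml"))
  expect_identical(length(man2$split$train), 7L)
  img <- png::readPNG(list.files(file.path(out, "images"), full.names = TRUE)[1])
  expect_identical(dim(img), c(96L, 96L, 3L))
  unlink(out, recursive = TRUE)
})
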