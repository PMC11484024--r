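test_that("confusion counts honour exclusion and ignore semantics", {
  # perfect prediction: no false positives or negatives
  gt <- matrix(sample(0:3, 100, TRUE), 10, 10)
  cc <- confusion(gt, gt, 3)
  expect_true(all(cc$fp == 0) && all(cc$fn == 0))
  # fully ignored ground truth scores nothing
  cc0 <- confusion(gt, matrix(255L, 10, 10), 3)
  expect_equal(cc0$valid_pixel_count, 0)
  expect_true(all(cc0$tp == 0) && all(cc0$fp == 0) && all(cc0$fn == 0))
  expect_error(confusion(matrix(0L, 2, 2), matrix(0L, 3, 3), 1), "shapes")
})

test_that("confusion matches the triple-loop oracle on random maps", {
  set.seed(30)
  for (rep in 1:20) {
    pred <- random_label_map(10, 10, 3, p255 = 0)
    gt <- random_label_map(10, 10, 3)
    cc <- confusion(pred, gt, 3)
    oc <- oracle_confusion(pred, gt, 3)
    expect_identical(cc$tp, oc$tp)
    expect_identical(cc$fp, oc$fp)
    expect_identical(cc$fn, oc$fn)
  }
})

test_that("mIoU reproduces the hand-built arithmetic case", {
  # class 1: TP 4, FP 2, FN 2 -> IoU 0.5; class 2: TP 6, FP 0, FN 2 -> 0.75
  gt <- matrix(255L, 4, 4)
  gt[1, ] <- 1L; gt[2, 1:2] <- 1L          # 6 pixels of class 1
  gt[3, ] <- 2L; gt[4, ] <- 2L             # 8 pixels of class 2
  pred <- gt
  pred[2, 1:2] <- 0L                       # 2 class-1 pixels missed (fn)
  pred[3, 1:2] <- 1L                       # 2 class-2 pixels claimed by 1:
                                           # fp for class 1, fn for class 2
  cc <- confusion(pred, gt, 2)
  expect_equal(unname(cc$tp), c(4, 6))
  expect_equal(unname(cc$fp), c(2, 0))
  expect_equal(unname(cc$fn), c(2, 2))
  ev <- miou(cc)
  expect_equal(unname(ev$per_class_iou), c(0.5, 0.75))
  expect_equal(ev$miou, 0.625)
})

test_that("mIoU limits: perfect prediction 1, disjoint single-class 0", {
  gt <- matrix(1L, 5, 5)
  expect_equal(miou(confusion(gt, gt, 1))$miou, 1)
  pred <- matrix(0L, 5, 5); pred[1:2, ] <- 1L
  gt2 <- matrix(0L, 5, 5); gt2[4:5, ] <- 1L
  expect_equal(suppressMessages(miou(confusion(pred, gt2, 1,
                                               excluded = integer(0))))$
                 per_class_iou[["1"]], 0)
  # classes absent from both maps are dropped, with a message
  gt3 <- matrix(1L, 4, 4)
  expect_message(ev <- miou(confusion(gt3, gt3, 3)), "dropped")
  expect_equal(ev$classes_scored, 1L)
  expect_error(miou(confusion(matrix(255L, 2, 2), matrix(255L, 2, 2), 1)),
               "scorable")
})

test_that("brute-force equivalence holds across an exhaustive small sweep", {
  # all 2^8 pairs of binary 2x2 pred/gt maps, background scored (K = 1)
  grids <- expand.grid(rep(list(0:1), 4))
  for (pi in seq_len(16)) for (gi in seq_len(16)) {
    pred <- matrix(as.integer(grids[pi, ]), 2, 2)
    gt <- matrix(as.integer(grids[gi, ]), 2, 2)
    cc <- confusion(pred, gt, 1, excluded = integer(0))
    oc <- oracle_confusion(pred, gt, 1, excluded = integer(0))
    expect_identical(cc$tp, oc$tp)
    expect_identical(cc$fp, oc$fp)
    expect_identical(cc$fn, oc$fn)
  }
})

test_that("mIoU is invariant to a consistent class relabelling", {
  set.seed(31)
  pred <- random_label_map(12, 12, 3, p255 = 0)
  gt <- random_label_map(12, 12, 3)
  ev1 <- suppressMessages(miou(confusion(pred, gt, 3)))
  # swap classes 1 and 3 in both maps
  sw <- function(m) { o <- m; o[m == 1L] <- 3L; o[m == 3L] <- 1L; o }
  ev2 <- suppressMessages(miou(confusion(sw(pred), sw(gt), 3)))
  expect_equal(sort(unname(ev1$per_class_iou)), sort(unname(ev2$per_class_iou)))
  expect_equal(ev1$miou, ev2$miou)
})

test_that("excluding a class does not perturb other classes' scoring", {
  set.seed(32)
  pred <- random_label_map(12, 12, 3, p255 = 0)
  gt <- random_label_map(12, 12, 3, p255 = 0)
  base <- confusion(pred, gt, 3, excluded = integer(0))
  excl <- confusion(pred, gt, 3, excluded = c(0L, 2L))
  # classes 1 and 3: TP and FN are untouched; FP can only shrink because
  # pixels whose GT is excluded leave the calculation area
  for (k in c("1", "3")) {
    expect_identical(excl$tp[[k]], base$tp[[k]])
    expect_identical(excl$fn[[k]], base$fn[[k]])
    expect_lte(excl$fp[[k]], base$fp[[k]])
  }
})

test_that("mask files round-trip losslessly and reject bad input", {
  dir <- withr::local_tempdir()
  m <- matrix(sample(c(0:3, 255L), 64, TRUE), 8, 8)
  path <- file.path(dir, "m.png")
  write_mask(m, path)
  expect_identical(read_mask(path), m)
  expect_identical(read_mask(path, n_classes = 3), m)
  expect_error(read_mask(path, n_classes = 1), "outside")
  expect_error(write_mask(matrix(-1, 2, 2), file.path(dir, "bad.png")),
               "0..255")
  # an RGB png is not a valid mask
  rgb <- file.path(dir, "rgb.png")
  png::writePNG(array(runif(12), c(2, 2, 3)), rgb)
  expect_error(read_mask(rgb), "grayscale")
})

test_that("overlay blends confident labels and passes 255 through", {
  img <- array(100L, c(4, 4, 3))
  pal <- rbind(c(0, 0, 0), c(200, 0, 0))
  lab <- matrix(255L, 4, 4)
  expect_identical(render_overlay(img, lab, pal), img)
  lab[2, 2] <- 1L
  ov <- render_overlay(img, lab, pal, alpha = 0.5)
  expect_identical(ov[2, 2, ], as.integer(round(0.5 * c(200, 0, 0) + 0.5 * 100)))
  expect_identical(ov[1, 1, ], c(100L, 100L, 100L))
  expect_identical(ov, render_overlay(img, lab, pal, alpha = 0.5))
})

test_that("directory evaluation pools counts and writes summaries", {
  dir <- withr::local_tempdir()
  pred_dir <- file.path(dir, "pred"); gt_dir <- file.path(dir, "gt")
  dir.create(pred_dir); dir.create(gt_dir)
  set.seed(33)
  for (f in c("a.png", "b.png")) {
    gt <- random_label_map(8, 8, 2, p255 = 0.1)
    pred <- gt; pred[1:2, ] <- random_label_map(2, 8, 2, p255 = 0)[, ]
    write_mask(gt, file.path(gt_dir, f))
    write_mask(pred, file.path(pred_dir, f))
  }
  oj <- file.path(dir, "ev.json"); oc <- file.path(dir, "ev.csv")
  ev <- evaluate_predictions(pred_dir, gt_dir, 2, out_json = oj, out_csv = oc)
  expect_s3_class(ev, "camseg_eval")
  js <- jsonlite::read_json(oj)
  expect_equal(js$miou, ev$miou, tolerance = 1e-12)
  expect_equal(js$n_images, 2)
  expect_equal(nrow(utils::read.csv(oc)), 2)
})
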