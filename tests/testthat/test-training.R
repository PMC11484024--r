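make_tiny_split <- function(n_train = 12, n_test = 4, size = 48, seed = 0) {
  benchmark_split(n_train = n_train, n_test = n_test, size = size, seed = seed)
}

tiny_train_cfg <- function(size = 48, epochs = 2, ...) {
  benchmark_train_config(size = size, epochs = epochs, batch_size = 4L,
                         crf_train_size = 24L, lambda_warmup_epochs = 1L,
                         ...)
}

tiny_model_cfg <- function(seed = 0) {
  camseg_config(n_classes = 3, channels = c(6L, 8L, 8L, 8L), d = 4L,
                decoder_width = 6L, seed = seed)
}

test_that("augmentation obeys crop geometry, identity and determinism", {
  p <- generate_dataset(synth_config(n_images = 1, seed = 2))[[1]]
  # the reference protocol's 513-crop: output is exactly 513 x 513
  big <- augment(p, train_config(crop_size = 513L, scale_range = c(2, 3)))
  expect_equal(dim(big$image), c(513, 513, 3))
  expect_equal(dim(big$gt_mask), c(513, 513))
  expect_true(all(big$gt_mask %in% c(0:3, 255L)))
  # scale 1 with crop = native size is the identity
  idcfg <- train_config(crop_size = 64L, scale_range = c(1, 1))
  same <- augment(p, idcfg)
  expect_identical(same$image, p$image)
  expect_identical(same$gt_mask, p$gt_mask)
  # a fixed RNG state reproduces the augmentation
  cfg <- train_config(crop_size = 40L, scale_range = c(1.5, 2.5))
  a1 <- withr::with_seed(5, augment(p, cfg))
  a2 <- withr::with_seed(5, augment(p, cfg))
  expect_identical(a1, a2)
})

test_that("joint training is deterministic under a fixed seed", {
  split <- make_tiny_split()
  cfg <- tiny_train_cfg()
  s1 <- train_joint(split$train, cfg, tiny_model_cfg())
  s2 <- train_joint(split$train, cfg, tiny_model_cfg())
  expect_equal(s1$history, s2$history, tolerance = 1e-12)
  expect_equal(s1$model$params, s2$model$params, tolerance = 1e-12)
})

test_that("lambda = 0 leaves decoder-only parameters untouched", {
  split <- make_tiny_split(n_train = 4)
  cfg <- tiny_train_cfg(epochs = 1, lambda = 0, lambda_warmup_epochs = 0L)
  mcfg <- tiny_model_cfg()
  st <- train_joint(split$train, cfg, mcfg)
  init <- camseg_model(mcfg)
  for (nm in c("dec1_W", "dec1_b", "dec2_W", "dec2_b", "dec3_W", "dec3_b"))
    expect_identical(st$model$params[[nm]], init$params[[nm]])
  # while classifier parameters did move
  expect_false(identical(st$model$params$da_W, init$params$da_W))
})

test_that("the loss-report identity holds at every logged step", {
  split <- make_tiny_split()
  st <- train_joint(split$train, tiny_train_cfg(lambda = 0.5),
                    tiny_model_cfg())
  h <- st$history
  expect_true(all(is.finite(h$L_total)))
  expect_lt(max(abs(h$L_seg - (h$L_ce + h$L_energy))), 1e-6)
  expect_lt(max(abs(h$L_total - (h$L_class + h$lambda * h$L_seg))), 1e-6)
})

test_that("empty datasets and label mismatches are rejected", {
  expect_error(train_joint(list(), tiny_train_cfg()), "empty")
  split <- make_tiny_split(n_train = 4)
  expect_error(train_joint(split$train, tiny_train_cfg(),
                           camseg_config(n_classes = 2)), "n_classes")
})

test_that("checkpoints round-trip bit-identically", {
  split <- make_tiny_split(n_train = 4)
  st <- train_joint(split$train, tiny_train_cfg(epochs = 1), tiny_model_cfg())
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(st, path)
  back <- load_checkpoint(path)
  expect_identical(back$model$params, st$model$params)
  expect_identical(back$train_config, st$train_config)
  # a model can be re-initialised from a checkpoint's weights
  m2 <- camseg_model(camseg_config(n_classes = 3,
                                   channels = c(6L, 8L, 8L, 8L), d = 4L,
                                   decoder_width = 6L, pretrained = TRUE,
                                   weights_file = path))
  expect_identical(m2$params$conv1_W, st$model$params$conv1_W)
  expect_error(camseg_config(pretrained = TRUE), "weights_file")
})

test_that("exported pseudo-labels stay in the label alphabet with a sidecar", {
  split <- make_tiny_split(n_train = 3)
  st <- train_joint(split$train, tiny_train_cfg(epochs = 1), tiny_model_cfg())
  dir <- withr::local_tempdir()
  df <- export_pseudo_labels(st, split$train, dir)
  files <- list.files(dir, pattern = "^pseudo.*png$")
  expect_length(files, 3)
  for (i in seq_along(files)) {
    m <- read_mask(file.path(dir, files[i]))
    expect_true(all(m %in% c(0:3, 255L)))
    # logged confident fraction matches a recount of the mask
    expect_equal(df$confident_fraction[i], mean(m != 255L), tolerance = 1e-12)
  }
  side <- jsonlite::read_json(file.path(dir, "pseudo_labels.json"))
  expect_equal(side$alpha, 0.3)
  expect_equal(side$beta, 0.9)
  # export is deterministic
  dir2 <- withr::local_tempdir()
  export_pseudo_labels(st, split$train, dir2)
  expect_identical(read_mask(file.path(dir, files[1])),
                   read_mask(file.path(dir2, files[1])))
  # an untrained state still exports, with a warning
  st0 <- camseg:::new_state(camseg_model(tiny_model_cfg()), tiny_train_cfg())
  expect_warning(export_pseudo_labels(st0, split$train[1],
                                      withr::local_tempdir()), "untrained")
})

test_that("standalone training validates masks and ignores 255-only images", {
  split <- make_tiny_split(n_train = 6)
  all255 <- lapply(split$train[1:2], function(p) {
    p$gt_mask <- matrix(255L, 48, 48); p
  })
  expect_error(train_standalone(all255, cfg = tiny_train_cfg()),
               "non-ignored")
  # a fully-ignored mask contributes exactly zero loss: training with it
  # present equals training without it when batches line up
  m <- camseg_model(tiny_model_cfg())
  x <- camseg:::patches_to_batch(all255[1])
  Fm <- camseg:::backbone_fwd(m, x)$F
  P <- camseg:::seg_fwd(m, Fm, 48, 48)
  ce <- camseg:::masked_ce_fwd(P$P, all255[[1]]$gt_mask)
  expect_identical(ce$loss, 0)
  expect_true(all(camseg:::masked_ce_dlogits(P$P, ce) == 0))
})

test_that("tiled prediction stitches without seams and averages overlaps", {
  m <- camseg_model(tiny_model_cfg())
  st <- camseg:::new_state(m, tiny_train_cfg())
  st$epoch <- 1L
  # a model whose prediction is position-independent (zero weights, fixed
  # decoder bias) isolates the stitcher: tiling a constant image must give
  # a constant label map with no seam artifacts
  mz <- m
  for (nm in grep("_W$", names(mz$params), value = TRUE))
    mz$params[[nm]][] <- 0
  mz$params$dec3_b <- c(0.1, 0.6, 0.2, -0.3)
  stz <- camseg:::new_state(mz, tiny_train_cfg())
  stz$epoch <- 1L
  img <- array(120L, c(40, 40, 3))
  lab <- predict(stz, img, test_scale = 1, tile_size = 24L, tile_overlap = 8L)
  expect_equal(dim(lab), c(40, 40))
  expect_identical(unique(as.vector(lab)), 2L)
  # image smaller than the tile uses a single window = plain forward pass
  img2 <- generate_dataset(synth_config(n_images = 1, seed = 9))[[1]]$image
  lab2 <- predict(st, img2, test_scale = 1, tile_size = 256L)
  Fm <- extract_features(m, camseg:::patches_to_batch(list(list(image = img2))))
  P <- seg_forward(m, Fm, c(64, 64))
  direct <- matrix(max.col(matrix(P, 64 * 64, 4), ties.method = "first"),
                   64, 64)
  direct[direct == 4] <- 0L
  expect_identical(lab2, matrix(as.integer(direct), 64, 64))
  # overlap probabilities equal the mean of the contributing tiles
  img3 <- generate_dataset(synth_config(n_images = 1, height = 32, width = 48,
                                        seed = 10))[[1]]$image
  Pst <- camseg:::predict_probs(m, img3, tile_size = 32L, tile_overlap = 16L)
  x1 <- array(img3[, 1:32, ] / 255, c(32, 32, 3, 1))
  x2 <- array(img3[, 17:48, ] / 255, c(32, 32, 3, 1))
  P1 <- seg_forward(m, extract_features(m, x1), c(32, 32))
  P2 <- seg_forward(m, extract_features(m, x2), c(32, 32))
  # columns 17..32 of the image are covered by both tiles
  ov <- (P1[, 17:32, , 1] + P2[, 1:16, , 1]) / 2
  expect_equal(Pst[, 17:32, ], ov, tolerance = 1e-12)
})

test_that("per-epoch pseudo-label refresh runs and logs consistently", {
  split <- make_tiny_split(n_train = 4)
  st <- train_joint(split$train,
                    tiny_train_cfg(epochs = 2, lambda_warmup_epochs = 0L,
                                   pseudo_label_refresh = "per_epoch"),
                    tiny_model_cfg())
  expect_true(all(is.finite(st$history$L_total)))
})
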