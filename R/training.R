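# Joint end-to-end optimisation of the classification and segmentation
# branches, pseudo-label export, standalone second-stage training, and
# tiled prediction.

#' Training configuration
#'
#' Optimisation defaults follow the reference protocol for this family of
#' weakly-supervised pipelines: SGD with batch size 8, initial learning rate
#' 0.001, weight decay 0.0002 and momentum 0.9; confidence thresholds
#' alpha = 0.3, beta = 0.9; training images are rescaled by a random factor
#' (default 2--3x) and cropped to \code{crop_size} (default 513); test
#' images are rescaled by \code{test_scale} (default 2.5) and tiled. Desk
#' scale experiments on small synthetic patches override the geometry
#' (crop = native size, no rescale, \code{test_scale = 1}).
#'
#' @param batch_size images per SGD step.
#' @param learning_rate,weight_decay,momentum SGD hyper-parameters.
#' @param epochs passes over the training set.
#' @param lambda weight of the segmentation loss in the total loss.
#' @param lambda_warmup_epochs minimum number of epochs with lambda = 0
#'   before the segmentation branch starts driving the shared backbone
#'   (0 = off).
#' @param lambda_warmup_loss optional classification-loss gate for the
#'   warm-up: after the minimum warm-up epochs, the segmentation loss stays
#'   off until the previous epoch's mean classification loss falls below
#'   this value, so the pseudo-labels only start supervising the decoder
#'   once the activation maps are trustworthy. \code{NULL} disables the
#'   gate (purely epoch-based warm-up).
#' @param thresholds a [threshold_config()].
#' @param crf a [crf_config()].
#' @param energy an [energy_config()].
#' @param use_crf refine pseudo-labels with the dense CRF (TRUE) or use the
#'   thresholded confidence map alone.
#' @param crf_train_size working size (longest image side, pixels) of the
#'   CRF run inside the training loop; exported pseudo-labels always use the
#'   full resolution.
#' @param crop_size training crop in pixels.
#' @param scale_range multiplicative rescale range applied before cropping.
#' @param test_scale test-time rescale factor.
#' @param tile_size,tile_overlap tiling of large test images, pixels.
#' @param pseudo_label_refresh \code{"per_batch"} (recompute pseudo-labels
#'   from the current activation maps at every step) or \code{"per_epoch"}.
#' @param clip_grad_norm clip the global gradient norm at this value
#'   before every update (default 5; \code{Inf} disables).
#' @param seg_backbone_mult multiplier on the segmentation branch's
#'   gradient where it enters the shared backbone. Values < 1 let the
#'   decoder train at full rate while the trunk — whose activation maps
#'   define the pseudo-labels — follows the segmentation loss only gently;
#'   the classification gradient, which maintains the activation maps,
#'   always reaches the trunk unscaled. Default 1 (fully joint).
#' @param lr_schedule \code{"poly"} (default) decays the learning rate as
#'   \code{learning_rate * (1 - t/T)^0.9} over the run, the schedule
#'   customary for dilated-decoder segmentation training;
#'   \code{"constant"} disables decay.
#' @param seed seed driving initialisation, shuffling and augmentation.
#' @param verbose print one structured log line per step.
#' @return a \code{train_config}.
#' @export
train_config <- function(batch_size = 8L, learning_rate = 0.001,
                         weight_decay = 2e-4, momentum = 0.9, epochs = 40L,
                         lambda = 1, lambda_warmup_epochs = 0L,
                         lambda_warmup_loss = NULL,
                         thresholds = threshold_config(), crf = crf_config(),
                         energy = energy_config(), use_crf = TRUE,
                         crf_train_size = 33L, crop_size = 513L,
                         scale_range = c(2, 3), test_scale = 2.5,
                         tile_size = 448L, tile_overlap = 64L,
                         pseudo_label_refresh = c("per_batch", "per_epoch"),
                         clip_grad_norm = 5, seg_backbone_mult = 1,
                         lr_schedule = c("poly", "constant"),
                         seed = 0L, verbose = FALSE) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (crop_size <= 0L) stop("crop_size must be > 0")
  if (scale_range[1] > scale_range[2]) stop("scale_range must be increasing")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 momentum = momentum, epochs = as.integer(epochs),
                 lambda = lambda,
                 lambda_warmup_epochs = as.integer(lambda_warmup_epochs),
                 lambda_warmup_loss = lambda_warmup_loss,
                 thresholds = thresholds, crf = crf, energy = energy,
                 use_crf = use_crf, crf_train_size = as.integer(crf_train_size),
                 crop_size = as.integer(crop_size),
                 scale_range = as.numeric(scale_range),
                 test_scale = test_scale, tile_size = as.integer(tile_size),
                 tile_overlap = as.integer(tile_overlap),
                 pseudo_label_refresh = match.arg(pseudo_label_refresh),
                 clip_grad_norm = clip_grad_norm,
                 seg_backbone_mult = seg_backbone_mult,
                 lr_schedule = match.arg(lr_schedule),
                 seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

# learning rate at a given 1-based step out of total
lr_at_step <- function(cfg, step, total) {
  if (identical(cfg$lr_schedule, "constant")) return(cfg$learning_rate)
  cfg$learning_rate * (1 - (step - 1) / total)^0.9
}


#' Rescale-and-crop augmentation
#'
#' The image is rescaled by a factor drawn uniformly from
#' \code{cfg$scale_range} (bilinear; any mask with nearest-neighbour) and
#' randomly cropped to \code{cfg$crop_size}, padding images with zeros and
#' masks with the ignore value 255 when the rescaled patch is smaller than
#' the crop. Uses the current RNG stream, so a fixed seed reproduces the
#' augmentation exactly.
#'
#' @param patch list with \code{image} (H x W x 3, 0..255) and optional
#'   \code{gt_mask}.
#' @param cfg a [train_config()].
#' @return augmented patch with a \code{crop_size}-square image.
#' @export
augment <- function(patch, cfg) {
  img <- patch$image
  H <- dim(img)[1]; W <- dim(img)[2]
  s <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
  H2 <- max(1L, as.integer(round(H * s))); W2 <- max(1L, as.integer(round(W * s)))
  identity_geom <- s == 1 && H2 == H && W2 == W
  if (!identity_geom) {
    img <- nn_resize_bilinear(img, H2, W2)
    if (!is.null(patch$gt_mask)) patch$gt_mask <- nn_resize_nearest(patch$gt_mask, H2, W2)
  }
  cs <- cfg$crop_size
  # pad (image with 0, mask with ignore) when smaller than the crop
  if (H2 < cs || W2 < cs) {
    Hp <- max(H2, cs); Wp <- max(W2, cs)
    pimg <- array(0, c(Hp, Wp, 3))
    pimg[seq_len(H2), seq_len(W2), ] <- img
    img <- pimg
    if (!is.null(patch$gt_mask)) {
      pm <- matrix(255L, Hp, Wp)
      pm[seq_len(H2), seq_len(W2)] <- patch$gt_mask
      patch$gt_mask <- pm
    }
    H2 <- Hp; W2 <- Wp
  }
  oy <- if (H2 > cs) sample.int(H2 - cs + 1L, 1L) else 1L
  ox <- if (W2 > cs) sample.int(W2 - cs + 1L, 1L) else 1L
  patch$image <- array(as.integer(round(pmin(pmax(
    img[oy + seq_len(cs) - 1L, ox + seq_len(cs) - 1L, , drop = FALSE],
    0), 255))), c(cs, cs, 3))
  if (!is.null(patch$gt_mask))
    patch$gt_mask <- patch$gt_mask[oy + seq_len(cs) - 1L,
                                   ox + seq_len(cs) - 1L]
  patch
}

# differentiable part of one joint step, with pseudo-labels held fixed.
# Returns the loss report, all parameter gradients, and P for inspection.
# `fixed_S` (list of H x W matrices, one per image) overrides the soft
# filter; used by the gradient tests, since S is treated as a constant in
# the backward pass (no gradient flows through the filter).
joint_forward_backward <- function(model, x, labels, pseudo, cfg,
                                   fixed_S = NULL, bf = NULL) {
  H <- dim(x)[1]; W <- dim(x)[2]; B <- dim(x)[4]
  lambda <- cfg$lambda
  if (is.null(bf)) bf <- backbone_fwd(model, x)
  cls <- classifier_fwd(model, bf$F)
  L_class <- classification_loss(cls$logits, labels)
  # with lambda = 0 the segmentation terms contribute nothing: skip them
  if (lambda != 0) {
    sf <- seg_fwd(model, bf$F, H, W)
    ce <- masked_ce_fwd(sf$P, pseudo)
    L_energy <- 0
    dP_energy <- array(0, dim(sf$P))
    for (n in seq_len(B)) {
      Pn <- array(sf$P[, , , n], dim(sf$P)[1:3])
      Sn <- if (is.null(fixed_S)) soft_filter(Pn, pseudo[, , n] != 255L)
            else fixed_S[[n]]
      en <- dense_energy_loss(Pn, array(x[, , , n], c(H, W, 3)), Sn,
                              cfg$energy, normalize = TRUE, return_grad = TRUE)
      L_energy <- L_energy + en$loss / B
      dP_energy[, , , n] <- en$dP / B
    }
    report <- loss_report(L_class, ce$loss, L_energy, lambda)
  } else {
    report <- loss_report(L_class, 0, 0, lambda)
  }
  # backward
  grads <- list()
  dlogits <- bce_grad(cls$logits, labels)
  cb <- classifier_bwd(model, dlogits, cls)
  for (nm in names(cb$grads)) grads <- nn_acc_grad(grads, nm, cb$grads[[nm]])
  dF <- cb$dF
  if (lambda != 0) {
    sb <- seg_bwd(model, lambda * dP_energy, sf,
                  dz_extra = lambda * masked_ce_dlogits(sf$P, ce))
    for (nm in names(sb$grads)) grads <- nn_acc_grad(grads, nm, sb$grads[[nm]])
    dF <- dF + (cfg$seg_backbone_mult %||% 1) * sb$dF
  }
  bb <- backbone_bwd(model, dF, bf$cache)
  for (nm in names(bb)) grads <- nn_acc_grad(grads, nm, bb[[nm]])
  list(report = report, grads = grads,
       P = if (lambda != 0) sf$P else NULL, Fmap = bf$F,
       logits = cls$logits)
}

# pseudo-labels for a batch from the current model (no gradient involved);
# `Fmap` lets callers reuse an already-computed feature map
batch_pseudo_labels <- function(model, x, cfg, Fmap = NULL) {
  B <- dim(x)[4]; H <- dim(x)[1]; W <- dim(x)[2]
  if (is.null(Fmap)) Fmap <- backbone_fwd(model, x)$F
  Mhat <- activation_scores(model, Fmap)
  pseudo <- array(255L, c(H, W, B))
  cf <- numeric(B)
  for (n in seq_len(B)) {
    pl <- make_pseudo_label(array(x[, , , n], c(H, W, 3)) * 255,
                            array(Mhat[, , , n], dim(Mhat)[1:3]),
                            cfg$thresholds, cfg$crf, cfg$use_crf,
                            cfg$crf_train_size)
    pseudo[, , n] <- pl$pseudo
    cf[n] <- pl$confident_fraction
  }
  list(pseudo = pseudo, confident_fraction = mean(cf))
}

new_state <- function(model, cfg, history = NULL, opt = list()) {
  structure(list(model = model, opt = opt, epoch = 0L,
                 train_config = cfg, history = history,
                 rng_state = NULL), class = "camseg_state")
}

#' @export
print.camseg_state <- function(x, ...) {
  cat(sprintf("camseg training state: %d epoch(s)", x$epoch))
  if (!is.null(x$history) && nrow(x$history))
    cat(sprintf(", final L_total = %.4f",
                x$history$L_total[nrow(x$history)]))
  cat("\n")
  invisible(x)
}

log_step <- function(cfg, row) {
  if (cfg$verbose)
    cat(sprintf(
      "step %d epoch %d L_class %.4f L_ce %.4f L_energy %.4f L_total %.4f conf %.3f\n",
      row$step, row$epoch, row$L_class, row$L_ce, row$L_energy, row$L_total,
      row$conf_frac))
}

#' Joint weakly-supervised training of both branches
#'
#' Per batch: the classification branch produces normalised activation maps;
#' pseudo-labels are built from them (confidence thresholding, optional
#' dense-CRF refinement, agreement fusion) with no gradient through their
#' construction; the segmentation branch is then supervised by masked
#' cross-entropy on confident pixels plus the dense energy loss; and the
#' total loss (classification + lambda x segmentation) is backpropagated
#' through both branches and the shared backbone. Only image-level labels
#' are consumed; ground-truth masks in the dataset are ignored.
#'
#' @param dataset a \code{camseg_dataset}: list of patches with
#'   \code{image} and multi-hot \code{label}.
#' @param cfg a [train_config()].
#' @param model_config a [camseg_config()]; its class count must match the
#'   dataset labels.
#' @param model optional \code{camseg_model} to start from (defaults to a
#'   fresh model built from \code{model_config}).
#' @return a \code{camseg_state} with the trained model, optimiser state and
#'   a per-step loss history (columns step, epoch, L_class, L_ce, L_energy,
#'   L_seg, L_total, lambda, conf_frac).
#' @export
train_joint <- function(dataset, cfg = train_config(),
                        model_config = NULL, model = NULL) {
  if (!length(dataset)) stop("empty dataset")
  K <- length(dataset[[1]]$label)
  if (is.null(model_config)) model_config <- camseg_config(n_classes = K)
  if (model_config$n_classes != K)
    stop("model n_classes does not match dataset labels")
  if (is.null(model)) model <- camseg_model(model_config)
  opt <- list()
  history <- list()
  step <- 0L
  total_steps <- cfg$epochs * ceiling(length(dataset) / cfg$batch_size)
  epoch_pseudo <- NULL
  rng_after <- NULL
  with_seed(cfg$seed, {
    prev_L_class <- Inf
    for (epoch in seq_len(cfg$epochs)) {
      warm <- epoch <= cfg$lambda_warmup_epochs
      if (!warm && !is.null(cfg$lambda_warmup_loss))
        warm <- prev_L_class > cfg$lambda_warmup_loss
      lambda_e <- if (warm) 0 else cfg$lambda
      cfg_e <- cfg; cfg_e$lambda <- lambda_e
      if (cfg$pseudo_label_refresh == "per_epoch" && lambda_e != 0) {
        # refresh once per epoch on the un-augmented images
        epoch_pseudo <- vector("list", length(dataset))
        for (n in seq_along(dataset)) {
          x1 <- patches_to_batch(dataset[n])
          epoch_pseudo[[n]] <- batch_pseudo_labels(model, x1, cfg)$pseudo[, , 1]
        }
      }
      ord <- sample.int(length(dataset))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (bi in batches) {
        # per-epoch refresh skips geometric augmentation so the cached
        # pseudo-labels stay aligned with the images
        aug <- if (cfg$pseudo_label_refresh == "per_epoch") dataset[bi]
               else lapply(dataset[bi], augment, cfg = cfg)
        x <- patches_to_batch(aug)
        labels <- do.call(rbind, lapply(aug, `[[`, "label"))
        bf <- backbone_fwd(model, x)
        if (lambda_e == 0) {
          # warm-up: the segmentation loss is off, no pseudo-labels needed
          pseudo <- array(255L, c(dim(x)[1], dim(x)[2], length(bi)))
          conf <- NA_real_
        } else if (cfg$pseudo_label_refresh == "per_epoch") {
          pseudo <- array(0L, c(dim(x)[1], dim(x)[2], length(bi)))
          for (j in seq_along(bi)) pseudo[, , j] <- epoch_pseudo[[bi[j]]]
          conf <- mean(pseudo != 255L)
        } else {
          bp <- batch_pseudo_labels(model, x, cfg, Fmap = bf$F)
          pseudo <- bp$pseudo
          conf <- bp$confident_fraction
        }
        res <- joint_forward_backward(model, x, labels, pseudo, cfg_e,
                                      bf = bf)
        if (!all(vapply(res$report, is.finite, logical(1))))
          stop("non-finite loss at step ", step + 1L,
               " (L_class = ", res$report$L_class, ")")
        up <- nn_sgd_update(model$params,
                            nn_clip_grads(res$grads, cfg$clip_grad_norm),
                            opt, lr_at_step(cfg, step + 1L, total_steps),
                            cfg$momentum, cfg$weight_decay)
        model$params <- up$params; opt <- up$opt
        step <- step + 1L
        row <- data.frame(step = step, epoch = epoch,
                          L_class = res$report$L_class,
                          L_ce = res$report$L_ce,
                          L_energy = res$report$L_energy,
                          L_seg = res$report$L_seg,
                          L_total = res$report$L_total,
                          lambda = lambda_e, conf_frac = conf)
        history[[step]] <- row
        log_step(cfg, row)
      }
      epoch_rows <- vapply(history, function(r) r$epoch == epoch, logical(1))
      prev_L_class <- mean(vapply(history[epoch_rows],
                                  function(r) r$L_class, numeric(1)))
    }
    rng_after <- get(".Random.seed", envir = globalenv())
  })
  st <- new_state(model, cfg, do.call(rbind, history), opt)
  st$epoch <- cfg$epochs
  st$rng_state <- rng_after
  st
}

#' Classification-only training
#'
#' Trains just the classification branch (backbone + activation layer +
#' attention + per-class heads, or the plain GAP classifier in the CAM-only
#' variant) with the multi-label binary cross-entropy loss. This is the
#' first stage of the two-step protocol and of the ablation runs.
#'
#' @inheritParams train_joint
#' @return a \code{camseg_state}; history has columns step, epoch, L_class.
#' @export
train_classifier <- function(dataset, cfg = train_config(),
                             model_config = NULL, model = NULL) {
  if (!length(dataset)) stop("empty dataset")
  K <- length(dataset[[1]]$label)
  if (is.null(model_config)) model_config <- camseg_config(n_classes = K)
  if (is.null(model)) model <- camseg_model(model_config)
  opt <- list(); history <- list(); step <- 0L
  total_steps <- cfg$epochs * ceiling(length(dataset) / cfg$batch_size)
  rng_after <- NULL
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(length(dataset))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (bi in batches) {
        aug <- lapply(dataset[bi], augment, cfg = cfg)
        x <- patches_to_batch(aug)
        labels <- do.call(rbind, lapply(aug, `[[`, "label"))
        bf <- backbone_fwd(model, x)
        cls <- classifier_fwd(model, bf$F)
        L <- classification_loss(cls$logits, labels)
        if (!is.finite(L)) stop("non-finite classification loss")
        cb <- classifier_bwd(model, bce_grad(cls$logits, labels), cls)
        grads <- cb$grads
        bb <- backbone_bwd(model, cb$dF, bf$cache)
        for (nm in names(bb)) grads <- nn_acc_grad(grads, nm, bb[[nm]])
        up <- nn_sgd_update(model$params,
                            nn_clip_grads(grads, cfg$clip_grad_norm),
                            opt, lr_at_step(cfg, step + 1L, total_steps),
                            cfg$momentum, cfg$weight_decay)
        model$params <- up$params; opt <- up$opt
        step <- step + 1L
        history[[step]] <- data.frame(step = step, epoch = epoch,
                                      L_class = L)
      }
    }
  rng_after <- get(".Random.seed", envir = globalenv())
  })
  st <- new_state(model, cfg, do.call(rbind, history), opt)
  st$epoch <- cfg$epochs
  st$rng_state <- rng_after
  st
}

#' Export fused pseudo-labels for a dataset
#'
#' Runs the trained classification branch over every image at native
#' resolution, builds the fused pseudo-label map with a full-resolution CRF,
#' and writes it as a grayscale PNG (values 0..K, 255). A JSON sidecar
#' records the thresholds, the CRF configuration and the per-image confident
#' fraction.
#'
#' @param state a trained \code{camseg_state}.
#' @param dataset patches to label.
#' @param out_dir output directory.
#' @param include_prediction also write the segmentation branch's argmax as
#'   \code{pred_*.png}.
#' @return (invisibly) data frame of per-image confident fractions.
#' @export
export_pseudo_labels <- function(state, dataset, out_dir,
                                 include_prediction = FALSE) {
  if (state$epoch == 0L)
    warning("exporting pseudo-labels from an untrained model")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- state$train_config
  rows <- vector("list", length(dataset))
  for (n in seq_along(dataset)) {
    p <- dataset[[n]]
    x <- patches_to_batch(list(p))
    Fmap <- backbone_fwd(state$model, x)$F
    Mhat <- activation_scores(state$model, Fmap)
    pl <- make_pseudo_label(p$image, array(Mhat, dim(Mhat)[1:3]),
                            cfg$thresholds, cfg$crf, cfg$use_crf,
                            crf_size = max(dim(p$image)[1:2]))
    f <- sprintf("pseudo_%04d.png", n)
    write_mask(pl$pseudo, file.path(out_dir, f))
    if (include_prediction) {
      lab <- predict(state, p$image, test_scale = 1)
      write_mask(lab, file.path(out_dir, sprintf("pred_%04d.png", n)))
    }
    rows[[n]] <- data.frame(filename = f,
                            confident_fraction = pl$confident_fraction)
  }
  df <- do.call(rbind, rows)
  jsonlite::write_json(
    list(alpha = cfg$thresholds$alpha, beta = cfg$thresholds$beta,
         crf = unclass(cfg$crf), use_crf = cfg$use_crf,
         confident_fraction = mean(df$confident_fraction),
         per_image = df),
    file.path(out_dir, "pseudo_labels.json"), auto_unbox = TRUE, digits = NA)
  invisible(df)
}

#' Standalone segmentation training on (pseudo-)masks
#'
#' Trains an independent encoder--decoder segmentation model with masked
#' cross-entropy, ignoring 255 pixels. When \code{labeled} patches with
#' trusted pixel masks are supplied they are mixed into training with equal
#' weight.
#'
#' @param dataset patches whose \code{gt_mask} holds the training masks
#'   (typically exported pseudo-labels; values 0..K, 255).
#' @param labeled optional additional patches with trusted masks.
#' @param cfg a [train_config()].
#' @param model_config a [camseg_config()].
#' @return a \code{camseg_state}.
#' @export
train_standalone <- function(dataset, labeled = NULL,
                             cfg = train_config(), model_config = NULL,
                             model = NULL) {
  data <- c(dataset, labeled)
  if (!length(data)) stop("empty dataset")
  if (all(vapply(data, function(p) all(p$gt_mask == 255L), logical(1))))
    stop("no non-ignored pixels in the entire dataset")
  K <- if (!is.null(model_config)) model_config$n_classes else
    max(1L, max(unlist(lapply(data, function(p) p$gt_mask[p$gt_mask != 255L]))))
  if (is.null(model_config)) model_config <- camseg_config(n_classes = K)
  if (is.null(model)) model <- camseg_model(model_config)
  opt <- list(); history <- list(); step <- 0L
  total_steps <- cfg$epochs * ceiling(length(data) / cfg$batch_size)
  rng_after <- NULL
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(length(data))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (bi in batches) {
        aug <- lapply(data[bi], augment, cfg = cfg)
        x <- patches_to_batch(aug)
        H <- dim(x)[1]; W <- dim(x)[2]
        pseudo <- array(255L, c(H, W, length(bi)))
        for (j in seq_along(aug)) pseudo[, , j] <- aug[[j]]$gt_mask
        bf <- backbone_fwd(model, x)
        sf <- seg_fwd(model, bf$F, H, W)
        ce <- masked_ce_fwd(sf$P, pseudo)
        if (!is.finite(ce$loss)) stop("non-finite segmentation loss")
        sb <- seg_bwd(model, array(0, dim(sf$P)), sf,
                      dz_extra = masked_ce_dlogits(sf$P, ce))
        grads <- sb$grads
        bb <- backbone_bwd(model, sb$dF, bf$cache)
        for (nm in names(bb)) grads <- nn_acc_grad(grads, nm, bb[[nm]])
        up <- nn_sgd_update(model$params,
                            nn_clip_grads(grads, cfg$clip_grad_norm),
                            opt, lr_at_step(cfg, step + 1L, total_steps),
                            cfg$momentum, cfg$weight_decay)
        model$params <- up$params; opt <- up$opt
        step <- step + 1L
        history[[step]] <- data.frame(step = step, epoch = epoch,
                                      L_ce = ce$loss)
      }
    }
  rng_after <- get(".Random.seed", envir = globalenv())
  })
  st <- new_state(model, cfg, do.call(rbind, history), opt)
  st$epoch <- cfg$epochs
  st$rng_state <- rng_after
  st
}

# stitched class-probability map for one image at its current size
predict_probs <- function(model, image, tile_size, tile_overlap) {
  H <- dim(image)[1]; W <- dim(image)[2]
  L <- model$config$n_classes + 1L
  x <- image / 255
  starts <- function(n, tile, stride) {
    if (n <= tile) return(1L)
    s <- seq(1L, n - tile + 1L, by = stride)
    unique(c(s, n - tile + 1L))
  }
  th <- min(tile_size, H); tw <- min(tile_size, W)
  stride <- max(1L, tile_size - tile_overlap)
  acc <- array(0, c(H, W, L)); cnt <- matrix(0, H, W)
  for (oy in starts(H, th, stride)) for (ox in starts(W, tw, stride)) {
    ys <- oy + seq_len(th) - 1L; xs <- ox + seq_len(tw) - 1L
    xb <- array(x[ys, xs, ], c(th, tw, 3, 1))
    Fm <- backbone_fwd(model, xb)$F
    P <- seg_fwd(model, Fm, th, tw)$P
    acc[ys, xs, ] <- acc[ys, xs, ] + array(P, c(th, tw, L))
    cnt[ys, xs] <- cnt[ys, xs] + 1
  }
  for (k in seq_len(L)) acc[, , k] <- acc[, , k] / cnt
  acc
}

#' Predict a segmentation label map for one image
#'
#' The image is rescaled by \code{test_scale}, tiled into overlapping
#' windows when larger than the tile size, per-tile class probabilities are
#' averaged in the overlaps, and the argmax label map is resized back to the
#' original resolution (background channel K+1 maps to label 0).
#'
#' @param object a \code{camseg_state} (or \code{camseg_model}).
#' @param image H x W x 3 RGB array, 0..255.
#' @param test_scale,tile_size,tile_overlap override the training
#'   configuration's test-time settings.
#' @param ... unused.
#' @return H x W integer label map over \{0..K\}.
#' @export
predict.camseg_state <- function(object, image, test_scale = NULL,
                                 tile_size = NULL, tile_overlap = NULL, ...) {
  cfg <- object$train_config
  predict_labels(object$model, image,
                 test_scale %||% cfg$test_scale,
                 tile_size %||% cfg$tile_size,
                 tile_overlap %||% cfg$tile_overlap)
}

predict_labels <- function(model, image, test_scale, tile_size,
                           tile_overlap) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (test_scale != 1) {
    image <- nn_resize_bilinear(image, as.integer(round(H * test_scale)),
                                as.integer(round(W * test_scale)))
  }
  P <- predict_probs(model, image, tile_size, tile_overlap)
  L <- dim(P)[3]
  lab <- max.col(matrix(P, dim(P)[1] * dim(P)[2], L), ties.method = "first")
  lab[lab == L] <- 0L
  lab <- matrix(as.integer(lab), dim(P)[1], dim(P)[2])
  if (!all(dim(lab) == c(H, W))) lab <- nn_resize_nearest(lab, H, W)
  lab
}

#' Evaluate a trained state on patches with ground-truth masks
#'
#' Predicts every patch and pools confusion counts; the background (label 0)
#' is excluded from scoring by default.
#'
#' @param state a \code{camseg_state}.
#' @param patches dataset with \code{gt_mask} fields.
#' @param excluded ground-truth labels excluded from scoring.
#' @param ... passed to [predict.camseg_state()].
#' @return a \code{camseg_eval}.
#' @export
evaluate_model <- function(state, patches, excluded = 0L, ...) {
  K <- state$model$config$n_classes
  pooled <- NULL
  for (p in patches) {
    lab <- predict(state, p$image, ...)
    pooled <- confusion_add(pooled, confusion(lab, p$gt_mask, K, excluded))
  }
  suppressMessages(miou(pooled))
}
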