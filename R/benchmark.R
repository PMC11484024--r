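# Desk-scale synthetic recovery experiments: train on generated
# toy-histology patches with image-level labels only and measure how much of
# the pixel-level ground truth the pipeline recovers. Shared by the test
# suite and the reproduction script.

#' Generate a train/held-out split of synthetic patches
#'
#' @param n_train,n_test patch counts.
#' @param size square patch size in pixels.
#' @param n_classes foreground class count.
#' @param seed base seed; the held-out set uses \code{seed + 10000}.
#' @return list with \code{train} and \code{test} datasets.
#' @export
benchmark_split <- function(n_train = 200L, n_test = 40L, size = 64L,
                            n_classes = 3L, seed = 0L) {
  list(train = generate_dataset(synth_config(n_images = n_train, height = size,
                                             width = size,
                                             n_classes = n_classes,
                                             seed = seed)),
       test = generate_dataset(synth_config(n_images = n_test, height = size,
                                            width = size,
                                            n_classes = n_classes,
                                            seed = seed + 10000L)))
}

#' Training configuration for the synthetic benchmark
#'
#' Keeps the reference optimisation family (SGD, batch 8, momentum 0.9,
#' weight decay 2e-4, alpha 0.3 / beta 0.9) and adapts the rest to small
#' from-scratch runs: crop = native size, no train or test rescaling, a
#' single prediction window, a higher base rate (0.03 — the reference 0.001
#' assumes a pre-trained backbone on 513-px crops), a 12-epoch
#' classification warm-up, and a 0.1 damping of the segmentation gradient
#' into the shared trunk (see the package vignette on training dynamics).
#'
#' @param size patch size in pixels.
#' @param epochs training epochs.
#' @param seed RNG seed.
#' @param ... further overrides passed to [train_config()].
#' @return a \code{train_config}.
#' @export
benchmark_train_config <- function(size = 64L, epochs = 40L, seed = 0L, ...) {
  args <- list(crop_size = as.integer(size), scale_range = c(1, 1),
               test_scale = 1, tile_size = as.integer(size),
               epochs = epochs, seed = seed,
               learning_rate = 0.03, lambda_warmup_epochs = 12L,
               seg_backbone_mult = 0.1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(train_config, args)
}

# replace gt_mask by the model's fused pseudo-labels (full-resolution CRF)
pseudo_dataset <- function(state, dataset) {
  cfg <- state$train_config
  out <- dataset
  for (n in seq_along(dataset)) {
    p <- dataset[[n]]
    Fmap <- backbone_fwd(state$model, patches_to_batch(list(p)))$F
    Mhat <- activation_scores(state$model, Fmap)
    pl <- make_pseudo_label(p$image, array(Mhat, dim(Mhat)[1:3]),
                            cfg$thresholds, cfg$crf, cfg$use_crf,
                            crf_size = max(dim(p$image)[1:2]))
    out[[n]]$gt_mask <- pl$pseudo
  }
  out
}

#' Run one synthetic weak-supervision experiment
#'
#' Modes:
#' \describe{
#'   \item{joint}{end-to-end joint training of both branches; the
#'     segmentation branch predicts directly.}
#'   \item{joint_two_step}{joint training, then fused pseudo-labels are
#'     exported and a fresh standalone segmentation model is trained on
#'     them.}
#'   \item{joint_two_step_mixed}{as \code{joint_two_step}, with an extra
#'     pixel-labelled set mixed into the standalone training.}
#'   \item{cls_cam}{classification-only training of a vanilla-CAM model (no
#'     discriminative-activation layer); pseudo-labels by thresholding the
#'     CAMs without CRF; standalone segmentation training.}
#'   \item{cls_da}{as \code{cls_cam} but with the discriminative-activation
#'     layer and attention classifier.}
#'   \item{cls_da_crf}{as \code{cls_da} plus dense-CRF fusion — the
#'     classic two-step pipeline.}
#'   \item{gt}{standalone training directly on the ground-truth masks (the
#'     fully-supervised ceiling).}
#' }
#'
#' @param mode experiment variant, see details.
#' @param split a [benchmark_split()].
#' @param epochs joint / classifier training epochs.
#' @param epochs_standalone standalone-stage epochs (defaults to
#'   \code{epochs}).
#' @param seed RNG seed for training.
#' @param n_labeled number of held-out-style labelled patches mixed in for
#'   \code{joint_two_step_mixed}.
#' @param verbose print per-step loss lines.
#' @return list with \code{miou}, the \code{camseg_eval}, and the final
#'   \code{state}.
#' @export
run_benchmark <- function(mode = c("joint", "joint_two_step",
                                   "joint_two_step_mixed", "cls_cam",
                                   "cls_da", "cls_da_crf", "gt"),
                          split, epochs = 40L,
                          epochs_standalone = epochs, seed = 0L,
                          n_labeled = 20L, verbose = FALSE) {
  mode <- match.arg(mode)
  size <- dim(split$train[[1]]$image)[1]
  K <- length(split$train[[1]]$label)
  cfg <- benchmark_train_config(size, epochs, seed, verbose = verbose)
  mcfg <- camseg_config(n_classes = K, seed = seed)
  if (mode == "joint") {
    st <- train_joint(split$train, cfg, mcfg)
    ev <- evaluate_model(st, split$test)
    return(list(miou = ev$miou, eval = ev, state = st))
  }
  if (mode == "gt") {
    cfg_s <- benchmark_train_config(size, epochs_standalone, seed)
    st <- train_standalone(split$train, cfg = cfg_s, model_config = mcfg)
    ev <- evaluate_model(st, split$test)
    return(list(miou = ev$miou, eval = ev, state = st))
  }
  if (mode %in% c("joint_two_step", "joint_two_step_mixed")) {
    st1 <- train_joint(split$train, cfg, mcfg)
  } else {
    cfg1 <- cfg
    cfg1$use_crf <- mode == "cls_da_crf"
    mcfg1 <- mcfg
    mcfg1$use_da <- mode != "cls_cam"
    st1 <- train_classifier(split$train, cfg1, mcfg1)
    st1$train_config <- cfg1
  }
  pd <- pseudo_dataset(st1, split$train)
  labeled <- NULL
  if (mode == "joint_two_step_mixed") {
    labeled <- generate_dataset(synth_config(n_images = n_labeled,
                                             height = size, width = size,
                                             n_classes = K,
                                             seed = seed + 20000L))
  }
  cfg_s <- benchmark_train_config(size, epochs_standalone, seed + 1L)
  mcfg_s <- camseg_config(n_classes = K, seed = seed + 1L)
  st2 <- train_standalone(pd, labeled, cfg_s, mcfg_s)
  ev <- evaluate_model(st2, split$test)
  list(miou = ev$miou, eval = ev, state = st2, stage1 = st1)
}
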