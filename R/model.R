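#' Model configuration for the two-branch weakly-supervised segmenter
#'
#' The model shares one convolutional backbone between a classification
#' branch (discriminative-activation layer, batch self-attention, per-class
#' binary heads) and a segmentation branch (dilated-convolution decoder over
#' the same features, softmaxed to K+1 per-pixel class probabilities).
#'
#' @param n_classes foreground class count K.
#' @param backbone_name \code{"tiny_cnn"} (4 strided conv layers, total
#'   stride 4) or \code{"tiny_resnet"} (same stem plus two residual blocks).
#' @param channels integer vector of the 4 backbone layer widths; the last
#'   entry is the feature width C shared by both branches.
#' @param d projection/embedding width of the self-attention layer.
#' @param decoder_width hidden width of the segmentation decoder.
#' @param attn_pool average-pooling factor applied to class feature maps
#'   before they are flattened into attention tokens (1 = no pooling). The
#'   classifier head only consumes a global average of the attended map, so
#'   pooling trades token-level granularity for speed.
#' @param shared_head use one shared weight vector over all classes'
#'   attended features (default) instead of per-class weights; the bias is
#'   per-class either way, so label priors are absorbed by the biases. With
#'   shared weights the only class-specific computation is the
#'   activation-map gating, so the gates are forced to become
#'   class-selective; per-class weights can classify even from spatially
#'   flat gates.
#' @param use_da if \code{FALSE}, the discriminative-activation layer and
#'   attention branch are replaced by a plain global-average-pool + linear
#'   classifier whose weights provide vanilla class activation maps (the
#'   CAM-only ablation).
#' @param pretrained must be \code{FALSE} unless \code{weights_file} points
#'   at a checkpoint to initialise from.
#' @param weights_file optional checkpoint path used as initialisation.
#' @param seed integer seed for parameter initialisation.
#' @return a \code{camseg_config}.
#' @export
camseg_config <- function(n_classes = 3L, backbone_name = "tiny_cnn",
                          channels = c(16L, 32L, 48L, 48L), d = 16L,
                          decoder_width = 32L, attn_pool = 2L,
                          shared_head = TRUE,
                          use_da = TRUE, pretrained = FALSE,
                          weights_file = NULL, seed = 0L) {
  if (n_classes < 1L) stop("n_classes must be >= 1")
  if (d < 1L) stop("d must be >= 1")
  if (!backbone_name %in% c("tiny_cnn", "tiny_resnet"))
    stop("unknown backbone_name: ", backbone_name)
  if (pretrained && is.null(weights_file))
    stop("pretrained = TRUE requires a weights_file checkpoint")
  structure(list(n_classes = as.integer(n_classes),
                 backbone_name = backbone_name,
                 channels = as.integer(channels), d = as.integer(d),
                 decoder_width = as.integer(decoder_width),
                 attn_pool = as.integer(attn_pool),
                 shared_head = isTRUE(shared_head), use_da = use_da,
                 pretrained = pretrained, weights_file = weights_file,
                 seed = as.integer(seed)),
            class = "camseg_config")
}

#' Initialise a model from a configuration
#'
#' Weights use He-normal initialisation under the configuration seed, so
#' identical configurations give identical models.
#'
#' @param config a [camseg_config()].
#' @return a \code{camseg_model} (list of \code{config} and \code{params}).
#' @export
camseg_model <- function(config) {
  stopifnot(inherits(config, "camseg_config"))
  K <- config$n_classes; ch <- config$channels
  C <- ch[4]; d <- config$d; dw <- config$decoder_width
  params <- with_seed(config$seed, {
    p <- list(
      conv1_W = nn_he_init(3 * 3 * 3, ch[1]),     conv1_b = numeric(ch[1]),
      conv2_W = nn_he_init(3 * 3 * ch[1], ch[2]), conv2_b = numeric(ch[2]),
      conv3_W = nn_he_init(3 * 3 * ch[2], ch[3]), conv3_b = numeric(ch[3]),
      conv4_W = nn_he_init(3 * 3 * ch[3], C),     conv4_b = numeric(C),
      da_W = nn_he_init(C, K + 1L), da_b = numeric(K + 1L),
      proj_W = nn_he_init(C, d), proj_b = numeric(d),
      attn_Wq = nn_he_init(d, d), attn_Wk = nn_he_init(d, d),
      attn_Wv = nn_he_init(d, d),
      head_W = nn_he_init(d, if (isTRUE(config$shared_head)) 1L else K),
      head_b = numeric(K),
      head0_W = nn_he_init(C, K), head0_b = numeric(K),
      dec1_W = nn_he_init(3 * 3 * C, dw), dec1_b = numeric(dw),
      dec2_W = nn_he_init(3 * 3 * dw, dw), dec2_b = numeric(dw),
      dec3_W = nn_he_init(dw, K + 1L), dec3_b = numeric(K + 1L))
    if (config$backbone_name == "tiny_resnet") {
      p$res1a_W <- nn_he_init(3 * 3 * C, C); p$res1a_b <- numeric(C)
      p$res1b_W <- nn_he_init(3 * 3 * C, C); p$res1b_b <- numeric(C)
      p$res2a_W <- nn_he_init(3 * 3 * C, C); p$res2a_b <- numeric(C)
      p$res2b_W <- nn_he_init(3 * 3 * C, C); p$res2b_b <- numeric(C)
    }
    p
  })
  model <- structure(list(config = config, params = params),
                     class = "camseg_model")
  if (!is.null(config$weights_file)) {
    st <- load_checkpoint(config$weights_file)
    common <- intersect(names(model$params), names(st$model$params))
    ok <- vapply(common, function(nm)
      identical(dim(model$params[[nm]]), dim(st$model$params[[nm]])) ||
        length(model$params[[nm]]) == length(st$model$params[[nm]]),
      logical(1))
    for (nm in common[ok]) model$params[[nm]] <- st$model$params[[nm]]
  }
  model
}

#' @export
print.camseg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("camseg model: backbone %s, K = %d, d = %d, %d parameters\n",
              x$config$backbone_name, x$config$n_classes, x$config$d,
              as.integer(np)))
  invisible(x)
}

# cached conv geometries, keyed by layer name + input size
model_geom <- function(env, key, H, W, Cin, k, stride, pad, dil = 1L) {
  id <- paste(key, H, W, Cin, k, stride, pad, dil, sep = "x")
  g <- env[[id]]
  if (is.null(g)) {
    g <- nn_conv_index(H, W, Cin, k, stride, pad, dil)
    env[[id]] <- g
  }
  g
}

the_geom_cache <- new.env(parent = emptyenv())

# ---- checkpoints ----------------------------------------------------------

CHECKPOINT_VERSION <- 1L

#' Save a training state (or bare model) to a single checkpoint file
#'
#' The file holds a version field, the configuration echo, all parameter
#' blobs, the optimiser state and the RNG state, so restarting from a
#' checkpoint is bit-identical.
#'
#' @param state a \code{camseg_state} from the training functions, or a bare
#'   \code{camseg_model}.
#' @param path output file.
#' @export
save_checkpoint <- function(state, path) {
  if (inherits(state, "camseg_model")) state <- list(model = state)
  payload <- list(version = CHECKPOINT_VERSION, model = state$model,
                  opt = state$opt, epoch = state$epoch,
                  train_config = state$train_config,
                  rng_state = state$rng_state, history = state$history)
  saveRDS(payload, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return the stored state list (fields \code{model}, \code{opt},
#'   \code{epoch}, \code{train_config}, \code{rng_state}, \code{history}).
#' @export
load_checkpoint <- function(path) {
  st <- readRDS(path)
  if (is.null(st$version) || st$version != CHECKPOINT_VERSION)
    stop("unsupported checkpoint version: ", st$version %||% "<missing>")
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a
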