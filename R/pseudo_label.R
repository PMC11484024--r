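# From normalised activation maps to reliable pixel pseudo-labels:
# confidence thresholding, dense-CRF refinement, and agreement fusion.

#' Confidence thresholds for pseudo-label seeding
#'
#' @param alpha background threshold in (0,1): a pixel whose maximum
#'   foreground score falls below \code{alpha} is a dependable background
#'   pixel. Default 0.3.
#' @param beta foreground threshold in (0,1): a pixel whose maximum
#'   foreground score exceeds \code{beta} keeps that class. Default 0.9.
#'   Requires \code{0 < alpha < beta < 1}.
#' @return a \code{threshold_config}.
#' @export
threshold_config <- function(alpha = 0.3, beta = 0.9) {
  if (!(alpha > 0 && alpha < beta && beta < 1))
    stop("thresholds must satisfy 0 < alpha < beta < 1")
  structure(list(alpha = alpha, beta = beta), class = "threshold_config")
}

#' Threshold activation maps into a confidence label map
#'
#' Per pixel, let k* be the foreground class with the largest normalised
#' score (ties broken by the lowest class index) and m its score. The pixel
#' becomes k* if m > beta, background (0) if m < alpha, and the ignore value
#' 255 otherwise. Background confidence is decided by the foreground maximum
#' falling below alpha, not by the background channel.
#'
#' @param Mhat normalised activation maps (H, W, K+1), already at the target
#'   (image) resolution.
#' @param cfg a [threshold_config()].
#' @return H x W integer label map over \{0..K, 255\}.
#' @export
confidence_map <- function(Mhat, cfg = threshold_config()) {
  d <- dim(Mhat)
  K <- d[3] - 1L
  hw <- d[1] * d[2]
  mm <- matrix(Mhat[, , seq_len(K)], hw, K)
  kstar <- max.col(mm, ties.method = "first")
  m <- mm[cbind(seq_len(hw), kstar)]
  out <- rep(255L, hw)
  out[m > cfg$beta] <- kstar[m > cfg$beta]
  out[m < cfg$alpha] <- 0L
  matrix(out, d[1], d[2])
}

#' Dense-CRF configuration
#'
#' Kernel defaults follow the values commonly used with seeded-region
#' weakly-supervised pipelines: a smoothness Gaussian on positions and an
#' appearance (bilateral) kernel on positions plus RGB colour.
#'
#' @param n_iterations mean-field iterations (default 5).
#' @param sigma_gamma spatial bandwidth of the smoothness kernel, pixels.
#' @param w1 smoothness kernel weight.
#' @param sigma_alpha spatial bandwidth of the appearance kernel, pixels.
#' @param sigma_beta colour bandwidth of the appearance kernel, 0..255 RGB
#'   units.
#' @param w2 appearance kernel weight.
#' @return a \code{crf_config}.
#' @export
crf_config <- function(n_iterations = 5L, sigma_gamma = 3, w1 = 3,
                       sigma_alpha = 80, sigma_beta = 13, w2 = 10) {
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (any(c(sigma_gamma, sigma_alpha, sigma_beta) <= 0))
    stop("kernel bandwidths must be > 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 sigma_gamma = sigma_gamma, w1 = w1,
                 sigma_alpha = sigma_alpha, sigma_beta = sigma_beta,
                 w2 = w2), class = "crf_config")
}

#' Dense-CRF refinement of activation maps
#'
#' Runs fully-connected mean-field inference with the activation scores as
#' unary potentials (renormalised to a distribution per pixel; all-zero
#' pixels get a uniform unary) and Gaussian smoothness plus bilateral
#' appearance pairwise kernels guided by the image. Deterministic for fixed
#' inputs and configuration.
#'
#' @param image H x W x 3 RGB array (0..255 integers, or [0,1] reals).
#' @param Mhat activation maps (h, w, K+1); upsampled bilinearly to the
#'   image size if the spatial sizes differ.
#' @param cfg a [crf_config()].
#' @return H x W integer label map over \{0..K\} (no 255 values): channel
#'   K+1 of the activation maps is the background and maps to label 0.
#' @export
crf_refine <- function(image, Mhat, cfg = crf_config()) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (max(image) <= 1) image <- image * 255
  if (!all(dim(Mhat)[1:2] == c(H, W)))
    Mhat <- nn_resize_bilinear(Mhat, H, W)
  L <- dim(Mhat)[3]
  q <- matrix(pmax(Mhat, 0), H * W, L)
  s <- rowSums(q)
  z <- s <= 1e-12
  q[!z, ] <- q[!z, , drop = FALSE] / s[!z]
  q[z, ] <- 1 / L
  img <- matrix(image, H * W, 3)
  Q <- cpp_crf_inference(q, img, H, W, cfg$n_iterations, cfg$sigma_gamma,
                         cfg$w1, cfg$sigma_alpha, cfg$sigma_beta, cfg$w2)
  lab <- max.col(Q, ties.method = "first")
  lab[lab == L] <- 0L                       # background channel -> label 0
  matrix(as.integer(lab), H, W)
}

#' Fuse confidence and CRF label maps into final pseudo-labels
#'
#' A pixel keeps its confidence label only where the CRF labelling agrees;
#' every disagreement (and every pixel already ignored by thresholding)
#' becomes the ignore value 255.
#'
#' @param p_r confidence label map from [confidence_map()].
#' @param p_crf CRF label map from [crf_refine()], same shape.
#' @return H x W integer label map over \{0..K, 255\}.
#' @export
fuse_pseudo_labels <- function(p_r, p_crf) {
  if (!all(dim(p_r) == dim(p_crf))) stop("label map shapes differ")
  out <- p_r
  out[p_r != p_crf] <- 255L
  out
}

# full per-image pseudo-label pipeline used inside training: upsample the
# feature-resolution scores to image size, threshold, optionally CRF-refine
# at a reduced working size, fuse. Returns the map plus bookkeeping.
make_pseudo_label <- function(image, Mhat_feat, tcfg, ccfg,
                              use_crf = TRUE, crf_size = 33L) {
  H <- dim(image)[1]; W <- dim(image)[2]
  Mhat_up <- nn_resize_bilinear(Mhat_feat, H, W)
  p_r <- confidence_map(Mhat_up, tcfg)
  if (use_crf) {
    if (max(H, W) > crf_size) {
      h2 <- max(8L, round(H * crf_size / max(H, W)))
      w2 <- max(8L, round(W * crf_size / max(H, W)))
      img_s <- nn_resize_bilinear(image, h2, w2)
      M_s <- nn_resize_bilinear(Mhat_up, h2, w2)
      p_crf <- crf_refine(img_s, M_s, ccfg)
      p_crf <- nn_resize_nearest(p_crf, H, W)
    } else {
      p_crf <- crf_refine(image, Mhat_up, ccfg)
    }
    pseudo <- fuse_pseudo_labels(p_r, p_crf)
  } else {
    pseudo <- p_r
  }
  list(pseudo = pseudo, p_r = p_r,
       confident_fraction = mean(pseudo != 255L))
}
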