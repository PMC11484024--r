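# Segmentation head over the shared backbone features, plus the loss
# surface: masked cross-entropy on confident pixels, soft filter, Gaussian
# dense pairwise energy, and their sum.

# ---- segmentation decoder -------------------------------------------------

seg_fwd <- function(model, Fmap, H, W) {
  p <- model$params; cfg <- model$config
  dF <- dim(Fmap)
  g1 <- model_geom(the_geom_cache, "d1", dF[1], dF[2], dF[3], 3L, 1L, 1L, 1L)
  c1 <- nn_conv_fwd(Fmap, p$dec1_W, p$dec1_b, g1); r1 <- nn_relu_fwd(c1$y)
  g2 <- model_geom(the_geom_cache, "d2", g1$Ho, g1$Wo, cfg$decoder_width,
                   3L, 1L, 2L, 2L)                  # dilation-2 (atrous) conv
  c2 <- nn_conv_fwd(r1$y, p$dec2_W, p$dec2_b, g2); r2 <- nn_relu_fwd(c2$y)
  c3 <- nn_conv1x1_fwd(r2$y, p$dec3_W, p$dec3_b)
  L <- cfg$n_classes + 1L
  B <- dF[4]
  Ry <- the_geom_cache[[paste0("Ry", dim(c3$y)[1], "to", H)]]
  if (is.null(Ry)) {
    Ry <- nn_resize_mat(dim(c3$y)[1], H)
    the_geom_cache[[paste0("Ry", dim(c3$y)[1], "to", H)]] <- Ry
  }
  Rx <- the_geom_cache[[paste0("Rx", dim(c3$y)[2], "to", W)]]
  if (is.null(Rx)) {
    Rx <- nn_resize_mat(dim(c3$y)[2], W)
    the_geom_cache[[paste0("Rx", dim(c3$y)[2], "to", W)]] <- Rx
  }
  P <- array(0, c(H, W, L, B))
  sm <- vector("list", B)
  for (n in seq_len(B)) {
    up <- nn_resize_bilinear(array(c3$y[, , , n], dim(c3$y)[1:3]), H, W, Ry, Rx)
    pm <- nn_softmax_rows(matrix(up, H * W, L))
    sm[[n]] <- pm
    P[, , , n] <- array(pm, c(H, W, L))
  }
  list(P = P, c1 = c1, r1 = r1, c2 = c2, r2 = r2, c3 = c3, sm = sm,
       Ry = Ry, Rx = Rx, H = H, W = W, L = L, hlo = dim(c3$y)[1],
       wlo = dim(c3$y)[2])
}

# dP: gradient w.r.t. the probabilities (routed through the softmax
# Jacobian); dz_extra: gradient already in logit space (used by the fused
# softmax + cross-entropy form, which stays bounded when P -> 0).
seg_bwd <- function(model, dP, cache, dz_extra = NULL) {
  p <- model$params
  B <- dim(dP)[4]; L <- cache$L
  dlog <- array(0, c(cache$hlo, cache$wlo, L, B))
  for (n in seq_len(B)) {
    dpm <- matrix(dP[, , , n], cache$H * cache$W, L)
    dz <- nn_softmax_rows_bwd(dpm, cache$sm[[n]])
    if (!is.null(dz_extra)) dz <- dz + matrix(dz_extra[, , , n],
                                              cache$H * cache$W, L)
    dup <- array(dz, c(cache$H, cache$W, L))
    dlog[, , , n] <- nn_resize_bilinear_bwd(dup, cache$hlo, cache$wlo,
                                            cache$Ry, cache$Rx)
  }
  b3 <- nn_conv1x1_bwd(dlog, cache$c3, p$dec3_W)
  d2 <- nn_relu_bwd(b3$dx, cache$r2)
  b2 <- nn_conv_bwd(d2, cache$c2, p$dec2_W)
  d1 <- nn_relu_bwd(b2$dx, cache$r1)
  b1 <- nn_conv_bwd(d1, cache$c1, p$dec1_W)
  list(dF = b1$dx,
       grads = list(dec3_W = b3$dW, dec3_b = b3$db, dec2_W = b2$dW,
                    dec2_b = b2$db, dec1_W = b1$dW, dec1_b = b1$db))
}

#' Segmentation forward pass
#'
#' Refines the backbone features through a small dilated-convolution decoder
#' to K+1 channel logits, bilinearly upsamples them to the requested output
#' resolution, and softmaxes per pixel, so every pixel carries a probability
#' simplex over the K foreground classes plus background (channel K+1).
#'
#' @param model a \code{camseg_model}.
#' @param features (H', W', C, B) backbone features.
#' @param out_size \code{c(H, W)} output resolution (the input image size).
#' @return array (H, W, K+1, B) of per-pixel class probabilities.
#' @export
seg_forward <- function(model, features, out_size) {
  seg_fwd(model, as_batch(features), out_size[1], out_size[2])$P
}

# ---- losses ---------------------------------------------------------------

#' Masked cross-entropy over the confident pseudo-label region
#'
#' Averages -log P at the pseudo-label class over all pixels whose
#' pseudo-label is not the ignore value 255 (label 0 = background reads the
#' background channel K+1). Returns 0 when no pixel is confident.
#'
#' @param P (H, W, K+1) or (H, W, K+1, B) prediction array.
#' @param pseudo matching (H, W) or (H, W, B) label map over \{0..K, 255\}.
#' @return scalar mean loss over confident pixels.
#' @export
masked_cross_entropy <- function(P, pseudo) {
  masked_ce_fwd(P, pseudo)$loss
}

label_to_channel <- function(lab, K) ifelse(lab == 0L, K + 1L, lab)

masked_ce_fwd <- function(P, pseudo, eps = 1e-12) {
  if (length(dim(P)) == 3L) dim(P) <- c(dim(P), 1L)
  if (length(dim(pseudo)) == 2L) dim(pseudo) <- c(dim(pseudo), 1L)
  d <- dim(P); K <- d[3] - 1L
  if (!all(dim(pseudo) == d[c(1, 2, 4)])) stop("P and pseudo shapes differ")
  if (any(pseudo != 255L & (pseudo < 0L | pseudo > K)))
    stop("pseudo-labels contain values outside {0..K, 255}")
  hw <- d[1] * d[2]; B <- d[4]
  idx_list <- vector("list", B)
  total <- 0
  nphi <- 0L
  for (n in seq_len(B)) {
    lab <- as.vector(pseudo[, , n])
    phi <- lab != 255L
    if (!any(phi)) next
    chan <- label_to_channel(lab[phi], K)
    pm <- matrix(P[, , , n], hw, K + 1L)
    ii <- cbind(which(phi), chan)
    total <- total + sum(-log(pmax(pm[ii], eps)))
    nphi <- nphi + sum(phi)
    idx_list[[n]] <- ii
  }
  loss <- if (nphi > 0L) total / nphi else 0
  list(loss = loss, idx = idx_list, nphi = nphi, dimP = d, eps = eps)
}

# fused softmax + masked-CE gradient in logit space: (P - onehot) / |phi|
# at confident pixels, zero elsewhere. Bounded even where P ~ 0.
masked_ce_dlogits <- function(P, cache) {
  d <- cache$dimP
  if (length(dim(P)) == 3L) dim(P) <- d
  dz <- array(0, d)
  if (cache$nphi == 0L) return(dz)
  hw <- d[1] * d[2]
  for (n in seq_len(d[4])) {
    ii <- cache$idx[[n]]
    if (is.null(ii)) next
    dm <- matrix(0, hw, d[3])
    pm <- matrix(P[, , , n], hw, d[3])
    rows <- ii[, 1]
    dm[rows, ] <- pm[rows, , drop = FALSE] / cache$nphi
    dm[ii] <- dm[ii] - 1 / cache$nphi
    dz[, , , n] <- array(dm, d[1:3])
  }
  dz
}

masked_ce_bwd <- function(P, cache) {
  d <- cache$dimP
  if (length(dim(P)) == 3L) dim(P) <- d
  dP <- array(0, d)
  if (cache$nphi == 0L) return(dP)
  hw <- d[1] * d[2]
  for (n in seq_len(d[4])) {
    ii <- cache$idx[[n]]
    if (is.null(ii)) next
    pm <- matrix(P[, , , n], hw, d[3])
    dm <- matrix(0, hw, d[3])
    dm[ii] <- -1 / (pmax(pm[ii], cache$eps) * cache$nphi)
    dP[, , , n] <- array(dm, d[1:3])
  }
  dP
}

#' Soft filter over the confident region
#'
#' S(i,j) = 1 - max_k P_k(i,j) on confident pixels (so pixels where the
#' model is already certain contribute little pairwise energy) and S = 1
#' everywhere else. The maximum runs over all K+1 output channels.
#'
#' @param P (H, W, K+1) prediction array for one image.
#' @param phi logical H x W matrix marking the confident region (pseudo-label
#'   != 255), or a pseudo-label map from which it is derived.
#' @return H x W matrix with values in [0, 1].
#' @export
soft_filter <- function(P, phi) {
  if (!is.logical(phi)) phi <- phi != 255L
  d <- dim(P)
  if (!all(dim(phi) == d[1:2])) stop("P and phi shapes differ")
  S <- matrix(1, d[1], d[2])
  mx <- matrix(nn_row_max(matrix(P, d[1] * d[2], d[3])), d[1], d[2])
  S[phi] <- 1 - mx[phi]
  S
}

#' Gaussian-kernel configuration of the dense pairwise energy
#'
#' @param sigma_pos spatial bandwidth in pixels (default 6).
#' @param sigma_rgb colour bandwidth on the [0,1] RGB scale (default 0.1).
#' @param radius neighbourhood truncation radius in pixels (default 5); the
#'   Gaussian kernel makes more distant pairs negligible.
#' @param weight kernel weight multiplying the normalised loss. The default,
#'   one over the neighbourhood pair count \code{(2 radius + 1)^2 - 1},
#'   makes the normalised loss a per-pair mean in [0, ~1], commensurate
#'   with the cross-entropy term regardless of the radius.
#' @return an \code{energy_config}.
#' @export
energy_config <- function(sigma_pos = 6, sigma_rgb = 0.1, radius = 5L,
                          weight = 1 / ((2 * radius + 1)^2 - 1)) {
  if (sigma_pos <= 0 || sigma_rgb <= 0) stop("bandwidths must be > 0")
  if (radius < 1L) stop("radius must be >= 1")
  structure(list(sigma_pos = sigma_pos, sigma_rgb = sigma_rgb,
                 radius = as.integer(radius), weight = weight),
            class = "energy_config")
}

#' Dense pairwise energy loss
#'
#' For every ordered pixel pair within the truncation radius, accumulates
#' \code{S(i) * G(i,j) * sum_\{k1 != k2\} P_k1(i) P_k2(j)} with a Gaussian
#' kernel G on positions and RGB colour, then divides by the pixel count and
#' applies the kernel weight (set \code{normalize = FALSE} for the raw
#' unweighted sum). The loss is zero exactly
#' when all pixels share one one-hot class, and penalises nearby
#' similar-coloured pixels that are assigned different classes.
#'
#' @param P (H, W, K+1) prediction array for one image.
#' @param image H x W x 3 RGB array (0..255 integers or [0,1] reals).
#' @param S H x W soft-filter matrix from [soft_filter()] (default all 1).
#' @param cfg an [energy_config()].
#' @param normalize divide by the number of pixels (default TRUE).
#' @param return_grad also return the gradient w.r.t. P.
#' @return scalar loss, or \code{list(loss, dP)} when \code{return_grad}.
#' @export
dense_energy_loss <- function(P, image, S = NULL, cfg = energy_config(),
                              normalize = TRUE, return_grad = FALSE) {
  d <- dim(P)
  if (max(image) > 1) image <- image / 255
  if (!all(dim(image)[1:2] == d[1:2])) stop("P and image shapes differ")
  if (is.null(S)) S <- matrix(1, d[1], d[2])
  res <- cpp_dense_energy(matrix(P, d[1] * d[2], d[3]),
                          matrix(image, d[1] * d[2], 3),
                          as.vector(S), d[1], d[2], cfg$radius,
                          cfg$sigma_pos, cfg$sigma_rgb, normalize)
  w <- if (normalize) cfg$weight %||% 1 else 1
  if (!return_grad) return(w * res$loss)
  list(loss = w * res$loss, dP = array(w * res$dP, d))
}

#' Total segmentation loss
#'
#' @param L_ce masked cross-entropy component.
#' @param L_energy dense energy component.
#' @return \code{L_ce + L_energy}.
#' @export
segmentation_loss <- function(L_ce, L_energy) {
  stopifnot(is.finite(L_ce), is.finite(L_energy))
  L_ce + L_energy
}

#' Assemble a per-step loss report
#'
#' @param L_class classification loss.
#' @param L_ce masked cross-entropy.
#' @param L_energy dense energy loss.
#' @param lambda weighting coefficient of the segmentation loss in the
#'   total.
#' @return list with all components, \code{L_seg = L_ce + L_energy} and
#'   \code{L_total = L_class + lambda * L_seg}.
#' @export
loss_report <- function(L_class, L_ce, L_energy, lambda = 1) {
  L_seg <- segmentation_loss(L_ce, L_energy)
  list(L_class = L_class, L_ce = L_ce, L_energy = L_energy, L_seg = L_seg,
       lambda = lambda, L_total = L_class + lambda * L_seg)
}
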