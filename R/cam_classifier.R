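# Classification branch: backbone features, discriminative-activation maps,
# batch self-attention over class-gated features, per-class binary heads.

# ---- backbone -------------------------------------------------------------

backbone_fwd <- function(model, x) {
  p <- model$params; ch <- model$config$channels
  x <- x - 0.5                      # centre [0,1] inputs
  d <- dim(x)
  g1 <- model_geom(the_geom_cache, "c1", d[1], d[2], 3L, 3L, 2L, 1L)
  c1 <- nn_conv_fwd(x, p$conv1_W, p$conv1_b, g1); r1 <- nn_relu_fwd(c1$y)
  g2 <- model_geom(the_geom_cache, "c2", g1$Ho, g1$Wo, ch[1], 3L, 2L, 1L)
  c2 <- nn_conv_fwd(r1$y, p$conv2_W, p$conv2_b, g2); r2 <- nn_relu_fwd(c2$y)
  g3 <- model_geom(the_geom_cache, "c3", g2$Ho, g2$Wo, ch[2], 3L, 1L, 1L)
  c3 <- nn_conv_fwd(r2$y, p$conv3_W, p$conv3_b, g3); r3 <- nn_relu_fwd(c3$y)
  g4 <- model_geom(the_geom_cache, "c4", g3$Ho, g3$Wo, ch[3], 3L, 1L, 1L)
  c4 <- nn_conv_fwd(r3$y, p$conv4_W, p$conv4_b, g4); r4 <- nn_relu_fwd(c4$y)
  cache <- list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, c3 = c3, r3 = r3,
                c4 = c4, r4 = r4)
  Fmap <- r4$y
  if (model$config$backbone_name == "tiny_resnet") {
    C <- ch[4]
    gr <- model_geom(the_geom_cache, "res", g4$Ho, g4$Wo, C, 3L, 1L, 1L)
    for (blk in c("res1", "res2")) {
      a <- nn_conv_fwd(Fmap, p[[paste0(blk, "a_W")]], p[[paste0(blk, "a_b")]], gr)
      ra <- nn_relu_fwd(a$y)
      b <- nn_conv_fwd(ra$y, p[[paste0(blk, "b_W")]], p[[paste0(blk, "b_b")]], gr)
      s <- nn_relu_fwd(Fmap + b$y)
      cache[[blk]] <- list(a = a, ra = ra, b = b, s = s)
      Fmap <- s$y
    }
  }
  list(F = Fmap, cache = cache)
}

backbone_bwd <- function(model, dF, cache) {
  p <- model$params
  grads <- list()
  if (model$config$backbone_name == "tiny_resnet") {
    for (blk in c("res2", "res1")) {
      cb <- cache[[blk]]
      ds <- nn_relu_bwd(dF, cb$s)
      bb <- nn_conv_bwd(ds, cb$b, p[[paste0(blk, "b_W")]])
      grads[[paste0(blk, "b_W")]] <- bb$dW
      grads[[paste0(blk, "b_b")]] <- bb$db
      dra <- nn_relu_bwd(bb$dx, cb$ra)
      ba <- nn_conv_bwd(dra, cb$a, p[[paste0(blk, "a_W")]])
      grads[[paste0(blk, "a_W")]] <- ba$dW
      grads[[paste0(blk, "a_b")]] <- ba$db
      dF <- ds + ba$dx            # skip connection
    }
  }
  d4 <- nn_relu_bwd(dF, cache$r4)
  b4 <- nn_conv_bwd(d4, cache$c4, p$conv4_W)
  d3 <- nn_relu_bwd(b4$dx, cache$r3)
  b3 <- nn_conv_bwd(d3, cache$c3, p$conv3_W)
  d2 <- nn_relu_bwd(b3$dx, cache$r2)
  b2 <- nn_conv_bwd(d2, cache$c2, p$conv2_W)
  d1 <- nn_relu_bwd(b2$dx, cache$r1)
  b1 <- nn_conv_bwd(d1, cache$c1, p$conv1_W)
  c(grads, list(conv4_W = b4$dW, conv4_b = b4$db, conv3_W = b3$dW,
                conv3_b = b3$db, conv2_W = b2$dW, conv2_b = b2$db,
                conv1_W = b1$dW, conv1_b = b1$db))
}

#' Extract backbone feature maps for a batch of images
#'
#' @param model a \code{camseg_model}.
#' @param images H x W x 3 x B array on the [0,1] scale (a single H x W x 3
#'   image is promoted to a batch of one). All images must share one size.
#' @return C x-channel feature array of dim (H', W', C, B) at backbone
#'   stride 4.
#' @export
extract_features <- function(model, images) {
  images <- as_batch(images)
  backbone_fwd(model, images)$F
}

as_batch <- function(images) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  if (length(dim(images)) != 4L) stop("images must be H x W x C [x B]")
  images
}

# stack a list of patches into an input batch on the [0,1] scale
patches_to_batch <- function(patches) {
  d <- dim(patches[[1]]$image)
  if (!all(vapply(patches, function(p) all(dim(p$image) == d), logical(1))))
    stop("all images in a batch must have the same size")
  x <- array(0, c(d, length(patches)))
  for (n in seq_along(patches)) x[, , , n] <- patches[[n]]$image / 255
  x
}

# ---- discriminative activation and per-pixel L2 normalisation --------------

#' Discriminative-activation maps
#'
#' A learnable 1x1 map from the backbone features to K+1 channels: one raw
#' activation map per foreground class plus an explicit background channel.
#'
#' @param model a \code{camseg_model}.
#' @param features (H', W', C, B) feature array from [extract_features()].
#' @return raw activation array of dim (H', W', K+1, B).
#' @export
discriminative_activation <- function(model, features) {
  nn_conv1x1_fwd(as_batch(features), model$params$da_W, model$params$da_b)$y
}

#' Per-pixel L2 normalisation of activation maps
#'
#' At every pixel the vector of absolute activations over the K+1 channels is
#' divided by its L2 norm, giving per-class scores in [0, 1] whose vector has
#' unit norm wherever the raw vector is nonzero; all-zero pixels map to zero
#' without NaNs.
#'
#' @param M raw activation array (H, W, K+1) or (H, W, K+1, B).
#' @return normalised array of the same shape.
#' @export
normalize_activation <- function(M) {
  normalize_activation_fwd(M)$y
}

normalize_activation_fwd <- function(M, eps = 1e-12) {
  d <- dim(M)
  single <- length(d) == 3L
  if (single) dim(M) <- c(d, 1L)
  a <- abs(M)
  L <- dim(M)[3]
  # per-pixel norms: reshape to (H*W, L, B)
  hw <- dim(M)[1] * dim(M)[2]
  B <- dim(M)[4]
  a3 <- array(a, c(hw, L, B))
  r <- matrix(0, hw, B)
  for (b in seq_len(B))
    r[, b] <- sqrt(rowSums(matrix(a3[, , b], hw, L)^2))
  rr <- r
  y3 <- array(0, dim(a3))
  nz <- rr > eps
  for (k in seq_len(L)) {
    yk <- a3[, k, ]
    yk <- matrix(yk, hw, dim(M)[4])
    yk[nz] <- yk[nz] / rr[nz]
    yk[!nz] <- 0
    y3[, k, ] <- yk
  }
  y <- array(y3, dim(M))
  if (single) {
    dim(y) <- d
  }
  list(y = y, M = M, a = a, r = r, eps = eps, single = single, dimy = dim(y))
}

normalize_activation_bwd <- function(dy, cache) {
  M <- cache$M; a <- cache$a; r <- cache$r; eps <- cache$eps
  d <- dim(M); hw <- d[1] * d[2]; L <- d[3]; B <- d[4]
  if (length(dim(dy)) == 3L) dim(dy) <- d
  dy3 <- array(dy, c(hw, L, B))
  a3 <- array(a, c(hw, L, B))
  dot <- matrix(0, hw, B)                # per-pixel <dy, a>
  for (b in seq_len(B))
    dot[, b] <- rowSums(matrix(dy3[, , b] * a3[, , b], hw, L))
  dm <- array(0, c(hw, L, B))
  for (b in seq_len(B)) {
    rb <- r[, b]
    nz <- rb > eps
    for (k in seq_len(L)) {
      g <- numeric(hw)
      g[nz] <- dy3[nz, k, b] / rb[nz] - dot[nz, b] * a3[nz, k, b] / rb[nz]^3
      dm[, k, b] <- g
    }
  }
  dm <- array(dm, d) * sign(M)
  if (cache$single) dim(dm) <- d[1:3]
  dm
}

#' Class-gated feature maps
#'
#' Multiplies every feature channel by the normalised activation of one
#' foreground class, producing the per-class features fed to the attention
#' layer. Gating uses foreground channels only; the background channel of
#' the activation map is not gated.
#'
#' @param features (H', W', C, B) backbone features.
#' @param Mhat (H', W', K+1, B) normalised activation maps.
#' @return list of K arrays, each (H', W', C, B).
#' @export
class_features <- function(features, Mhat) {
  features <- as_batch(features); Mhat <- as_batch(Mhat)
  if (!all(dim(features)[c(1, 2, 4)] == dim(Mhat)[c(1, 2, 4)]))
    stop("features and activation maps are not spatially aligned")
  K <- dim(Mhat)[3] - 1L
  C <- dim(features)[3]
  lapply(seq_len(K), function(k) {
    gate <- Mhat[, , k, , drop = FALSE]
    features * gate[, , rep(1L, C), , drop = FALSE]
  })
}

# ---- batch self-attention pooling -----------------------------------------

# forward over one class's stacked features; tokens are all B x Hp x Wp
# spatial positions of the (optionally pooled) projected maps.
attention_fwd <- function(model, Fk, pool = 1L) {
  p <- model$params
  d4 <- dim(Fk); B <- d4[4]
  pools <- vector("list", B)
  Xs <- vector("list", B)
  for (n in seq_len(B)) {
    pl <- nn_avgpool_fwd(array(Fk[, , , n], d4[1:3]), pool)
    pools[[n]] <- pl
    Xs[[n]] <- matrix(pl$y, nrow = dim(pl$y)[1] * dim(pl$y)[2])
  }
  Tn <- nrow(Xs[[1]])
  X <- do.call(rbind, Xs)
  proj <- sweep(X %*% p$proj_W, 2L, p$proj_b, `+`)
  at <- nn_attn_fwd(proj, p$attn_Wq, p$attn_Wk, p$attn_Wv)
  # residual connection: attended features refine, not replace, the
  # projection (without it, diffuse early attention collapses every token
  # to the batch mean and the classifier can only learn label priors)
  list(Y = proj + at$y, at = at, X = X, pools = pools, Tn = Tn, B = B,
       Hp = dim(pools[[1]]$y)[1], Wp = dim(pools[[1]]$y)[2])
}

attention_bwd <- function(model, dY, cache) {
  p <- model$params
  ab <- nn_attn_bwd(dY, cache$at, p$attn_Wq, p$attn_Wk, p$attn_Wv)
  dproj <- dY + ab$dX                       # residual path
  dX <- dproj %*% t(p$proj_W)
  grads <- list(proj_W = crossprod(cache$X, dproj), proj_b = colSums(dproj),
                attn_Wq = ab$dWq, attn_Wk = ab$dWk, attn_Wv = ab$dWv)
  B <- cache$B; Tn <- cache$Tn
  dFk <- NULL
  for (n in seq_len(B)) {
    dn <- dX[(n - 1L) * Tn + seq_len(Tn), , drop = FALSE]
    dpool <- array(dn, c(cache$Hp, cache$Wp, ncol(dn)))
    dfn <- nn_avgpool_bwd(dpool, cache$pools[[n]])
    if (is.null(dFk)) dFk <- array(0, c(dim(dfn), B))
    dFk[, , , n] <- dfn
  }
  list(dFk = dFk, grads = grads)
}

#' Batch self-attention pooling of class-gated features
#'
#' Projects one class's stacked feature maps to width d with a shared 1x1
#' map, flattens the spatial positions of every image in the batch into one
#' token sequence, applies a single scaled dot-product self-attention pass
#' (so the attention mixes information within and between images), and splits
#' the result back into per-image attended maps. With B = 1 this degenerates
#' to within-image attention.
#'
#' @param model a \code{camseg_model}.
#' @param class_feat (H', W', C, B) gated features for one class.
#' @param pool optional average-pooling factor applied before tokenisation
#'   (default 1 = none).
#' @return attended maps, array (Hp, Wp, d, B).
#' @export
self_attention_pool <- function(model, class_feat, pool = 1L) {
  cf <- attention_fwd(model, as_batch(class_feat), pool)
  A <- array(0, c(cf$Hp, cf$Wp, ncol(cf$Y), cf$B))
  for (n in seq_len(cf$B))
    A[, , , n] <- array(cf$Y[(n - 1L) * cf$Tn + seq_len(cf$Tn), ],
                        c(cf$Hp, cf$Wp, ncol(cf$Y)))
  A
}

#' Per-class classification logits from attended features
#'
#' Global average pooling over the spatial positions of each attended map,
#' followed by a class-specific affine map to one scalar logit.
#'
#' @param model a \code{camseg_model}.
#' @param attended list of K arrays (Hp, Wp, d, B) as produced by
#'   [self_attention_pool()] per class.
#' @return B x K logit matrix.
#' @export
classification_scores <- function(model, attended) {
  K <- length(attended)
  B <- dim(as_batch(attended[[1]]))[4]
  logits <- matrix(0, B, K)
  shared <- isTRUE(model$config$shared_head)
  for (k in seq_len(K)) {
    A <- as_batch(attended[[k]])
    g <- t(apply(A, c(3, 4), mean))            # B x d
    if (dim(A)[4] == 1L) g <- matrix(apply(A, 3, mean), 1L)
    hk <- if (shared) 1L else k
    logits[, k] <- g %*% model$params$head_W[, hk] + model$params$head_b[k]
  }
  logits
}

#' Multi-label classification loss (mean binary cross-entropy)
#'
#' The K-class multi-label problem is treated as K independent binary
#' problems; the loss is the mean over all (image, class) pairs of the
#' binary cross-entropy with logits.
#'
#' @param logits B x K matrix of per-class logits.
#' @param labels B x K multi-hot 0/1 matrix.
#' @return scalar loss (>= 0).
#' @export
classification_loss <- function(logits, labels) {
  labels <- as.matrix(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1)")
  if (!all(dim(logits) == dim(labels))) stop("logits/labels shapes differ")
  # stable softplus form of BCE-with-logits
  z <- as.matrix(logits)
  mean(pmax(z, 0) - z * labels + log1p(exp(-abs(z))))
}

bce_grad <- function(logits, labels) {
  (1 / (1 + exp(-logits)) - labels) / length(labels)
}

# full classification-branch forward with caches (internal, used by training)
classifier_fwd <- function(model, Fmap, pool = NULL) {
  cfg <- model$config
  if (is.null(pool)) pool <- cfg$attn_pool
  K <- cfg$n_classes
  B <- dim(Fmap)[4]
  if (!cfg$use_da) {
    # vanilla CAM: GAP + linear heads; maps come from the head weights
    g <- t(apply(Fmap, c(3, 4), mean))
    if (B == 1L) g <- matrix(apply(Fmap, 3, mean), 1L)
    logits <- sweep(g %*% model$params$head0_W, 2L, model$params$head0_b, `+`)
    return(list(logits = logits, mode = "cam", g = g, Fmap = Fmap))
  }
  norm <- normalize_activation_fwd(
    nn_conv1x1_fwd(Fmap, model$params$da_W, model$params$da_b)$y)
  Mhat <- norm$y
  C <- dim(Fmap)[3]
  ks <- vector("list", K)
  logits <- matrix(0, B, K)
  shared <- isTRUE(cfg$shared_head)
  for (k in seq_len(K)) {
    gate <- array(Mhat[, , k, ], c(dim(Mhat)[1], dim(Mhat)[2], 1L, B))
    Fk <- Fmap * gate[, , rep(1L, C), , drop = FALSE]
    at <- attention_fwd(model, Fk, pool)
    Tn <- at$Tn
    gk <- matrix(0, B, ncol(at$Y))
    for (n in seq_len(B))
      gk[n, ] <- colMeans(at$Y[(n - 1L) * Tn + seq_len(Tn), , drop = FALSE])
    hk <- if (shared) 1L else k
    logits[, k] <- gk %*% model$params$head_W[, hk] + model$params$head_b[k]
    ks[[k]] <- list(at = at, gk = gk, gate = gate, hk = hk)
  }
  list(logits = logits, mode = "da", norm = norm, Mhat = Mhat, ks = ks,
       Fmap = Fmap)
}

# backward of the classification branch given dlogits; returns parameter
# grads plus the gradient reaching the shared features.
classifier_bwd <- function(model, dlogits, cache) {
  p <- model$params
  if (cache$mode == "cam") {
    B <- nrow(dlogits)
    grads <- list(head0_W = crossprod(cache$g, dlogits),
                  head0_b = colSums(dlogits))
    dg <- dlogits %*% t(p$head0_W)               # B x C
    dF <- array(0, dim(cache$Fmap))
    hw <- dim(cache$Fmap)[1] * dim(cache$Fmap)[2]
    for (n in seq_len(B))
      dF[, , , n] <- array(rep(dg[n, ] / hw, each = hw), dim(cache$Fmap)[1:3])
    return(list(grads = grads, dF = dF))
  }
  K <- model$config$n_classes
  B <- nrow(dlogits)
  Fmap <- cache$Fmap
  C <- dim(Fmap)[3]
  grads <- list(head_W = matrix(0, nrow(p$head_W), ncol(p$head_W)),
                head_b = numeric(K))
  dF <- array(0, dim(Fmap))
  dMhat <- array(0, dim(cache$Mhat))
  for (k in seq_len(K)) {
    kc <- cache$ks[[k]]
    hk <- kc$hk
    grads$head_W[, hk] <- grads$head_W[, hk] + crossprod(kc$gk, dlogits[, k])
    grads$head_b[k] <- grads$head_b[k] + sum(dlogits[, k])
    dgk <- dlogits[, k] %o% p$head_W[, hk]       # B x d
    Tn <- kc$at$Tn
    dY <- matrix(0, Tn * B, ncol(dgk))
    for (n in seq_len(B))
      dY[(n - 1L) * Tn + seq_len(Tn), ] <-
        matrix(dgk[n, ], Tn, ncol(dgk), byrow = TRUE) / Tn
    ab <- attention_bwd(model, dY, kc$at)
    for (nm in names(ab$grads)) grads <- nn_acc_grad(grads, nm, ab$grads[[nm]])
    gate <- kc$gate[, , rep(1L, C), , drop = FALSE]
    prod <- ab$dFk * Fmap
    dF <- dF + ab$dFk * gate
    csum <- prod[, , 1L, , drop = FALSE]
    for (cc in seq_len(C)[-1L]) csum <- csum + prod[, , cc, , drop = FALSE]
    dMhat[, , k, ] <- dMhat[, , k, ] + array(csum, dim(csum)[c(1, 2, 4)])
  }
  dM <- normalize_activation_bwd(dMhat, cache$norm)
  da <- nn_conv1x1_bwd(dM, nn_conv1x1_fwd(Fmap, p$da_W, p$da_b), p$da_W)
  grads$da_W <- da$dW; grads$da_b <- da$db
  dF <- dF + da$dx
  list(grads = grads, dF = dF)
}

# normalised (0..1) K+1-channel score maps used for pseudo-labelling, for
# either model variant. CAM variant: relu(w_k * F) scaled by the per-image
# max over foreground channels; background = 1 - max_k score.
activation_scores <- function(model, Fmap) {
  if (model$config$use_da) {
    return(normalize_activation(
      nn_conv1x1_fwd(Fmap, model$params$da_W, model$params$da_b)$y))
  }
  K <- model$config$n_classes
  raw <- nn_conv1x1_fwd(Fmap, model$params$head0_W,
                        numeric(K))$y              # CAM without bias
  raw <- pmax(raw, 0)
  d <- dim(raw); B <- d[4]
  out <- array(0, c(d[1], d[2], K + 1L, B))
  for (n in seq_len(B)) {
    mx <- max(raw[, , , n])
    sc <- if (mx > 0) array(raw[, , , n], d[1:3]) / mx else array(0, d[1:3])
    out[, , seq_len(K), n] <- sc
    out[, , K + 1L, n] <- pmax(0, 1 - apply(sc, c(1, 2), max))
  }
  out
}
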