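# Minimal neural-network primitives (forward + manual backward).
#
# Conventions:
#   * single feature map: array dim c(H, W, C); batch: array dim c(H, W, C, B)
#   * conv weight: matrix (k*k*Cin) x Cout, patch columns ordered (ky, kx, c)
#     with ky fastest, matching the im2col index construction below
#   * all gradients are exact (validated by finite differences in the tests)

# ---- seeded evaluation without clobbering the caller's RNG ----------------

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- im2col convolution ---------------------------------------------------

# Linear indices into the zero-padded input for every (output position, patch
# element) pair. Depends only on geometry, so callers cache it.
nn_conv_index <- function(H, W, Cin, k, stride, pad, dilation = 1L) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  span <- (k - 1L) * dilation + 1L
  Ho <- (Hp - span) %/% stride + 1L
  Wo <- (Wp - span) %/% stride + 1L
  oy <- rep(seq_len(Ho), times = Wo)
  ox <- rep(seq_len(Wo), each = Ho)
  base <- (oy - 1L) * stride + 1L + ((ox - 1L) * stride) * Hp  # top-left, ch 1
  ky <- rep(seq_len(k) - 1L, times = k * Cin)
  kx <- rep(rep(seq_len(k) - 1L, each = k), times = Cin)
  ch <- rep(seq_len(Cin) - 1L, each = k * k)
  off <- ky * dilation + kx * dilation * Hp + ch * (Hp * Wp)
  idx <- outer(base, off, `+`)
  # transpose scatter operator for col2im: dxp = St %*% vec(dcols)
  St <- Matrix::sparseMatrix(i = as.vector(idx), j = seq_along(idx), x = 1,
                             dims = c(Hp * Wp * Cin, length(idx)))
  list(idx = idx, St = St, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp,
       H = H, W = W, Cin = Cin, k = k, stride = stride, pad = pad,
       dilation = dilation)
}

nn_pad <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

# x: (H, W, Cin, B); Wm: (k^2*Cin) x Cout. Returns y (Ho, Wo, Cout, B).
# Patch matrices for the whole batch are stacked so the product with the
# kernel is a single BLAS call.
nn_conv_fwd <- function(x, Wm, b, geom) {
  B <- dim(x)[4]; Cout <- ncol(Wm)
  hw <- geom$Ho * geom$Wo
  cols <- matrix(0, hw * B, nrow(Wm))
  for (n in seq_len(B)) {
    xp <- nn_pad(array(x[, , , n], dim(x)[1:3]), geom$pad)
    cols[(n - 1L) * hw + seq_len(hw), ] <- xp[geom$idx]
  }
  out <- cols %*% Wm
  out <- out + rep(b, each = nrow(out))
  # rows are (spatial, image); reorder into (Ho, Wo, Cout, B)
  y <- aperm(array(out, c(hw, B, Cout)), c(1, 3, 2))
  dim(y) <- c(geom$Ho, geom$Wo, Cout, B)
  list(y = y, cols = cols, geom = geom, dimx = dim(x))
}

nn_conv_bwd <- function(dy, cache, Wm) {
  geom <- cache$geom; B <- dim(dy)[4]
  hw <- geom$Ho * geom$Wo
  Cout <- ncol(Wm)
  dyn <- array(dy, c(hw, Cout, B))
  dyn <- matrix(aperm(dyn, c(1, 3, 2)), hw * B, Cout)
  dW <- crossprod(cache$cols, dyn)
  db <- colSums(dyn)
  dcols <- dyn %*% t(Wm)
  dx <- array(0, cache$dimx)
  p <- geom$pad
  for (n in seq_len(B)) {
    dxp <- array(as.vector(geom$St %*%
                             as.vector(dcols[(n - 1L) * hw + seq_len(hw), ])),
                 c(geom$Hp, geom$Wp, geom$Cin))
    dx[, , , n] <- dxp[p + seq_len(geom$H), p + seq_len(geom$W), , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# 1x1 convolution: per-pixel linear map, one matmul for the whole batch.
nn_conv1x1_fwd <- function(x, Wm, b) {
  d <- dim(x); B <- d[4]; Cout <- ncol(Wm)
  hw <- d[1] * d[2]
  xm <- matrix(aperm(array(x, c(hw, d[3], B)), c(1, 3, 2)), hw * B, d[3])
  out <- xm %*% Wm
  out <- out + rep(b, each = nrow(out))
  y <- aperm(array(out, c(hw, B, Cout)), c(1, 3, 2))
  dim(y) <- c(d[1], d[2], Cout, B)
  list(y = y, xm = xm, dimx = d)
}

nn_conv1x1_bwd <- function(dy, cache, Wm) {
  d <- cache$dimx; B <- d[4]; Cout <- ncol(Wm)
  hw <- d[1] * d[2]
  dyn <- matrix(aperm(array(dy, c(hw, Cout, B)), c(1, 3, 2)), hw * B, Cout)
  dW <- crossprod(cache$xm, dyn)
  db <- colSums(dyn)
  dxm <- dyn %*% t(Wm)
  dx <- aperm(array(dxm, c(hw, B, d[3])), c(1, 3, 2))
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

nn_relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
nn_relu_bwd <- function(dy, cache) dy * cache$mask

# ---- resizing -------------------------------------------------------------

# Bilinear interpolation matrix (n_out x n_in), half-pixel centre alignment.
nn_resize_mat <- function(n_in, n_out) {
  R <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5   # 0-based source coord
  i0 <- floor(src)
  w <- src - i0
  i0c <- pmin(pmax(i0, 0), n_in - 1)
  i1c <- pmin(i0 + 1, n_in - 1)
  i1c <- pmax(i1c, 0)
  for (i in seq_len(n_out)) {
    R[i, i0c[i] + 1] <- R[i, i0c[i] + 1] + (1 - w[i])
    R[i, i1c[i] + 1] <- R[i, i1c[i] + 1] + w[i]
  }
  R
}

# x: (H, W, C) -> (H2, W2, C); returns value only (backward uses transposes).
nn_resize_bilinear <- function(x, H2, W2, Ry = NULL, Rx = NULL) {
  d <- dim(x)
  if (is.null(Ry)) Ry <- nn_resize_mat(d[1], H2)
  if (is.null(Rx)) Rx <- nn_resize_mat(d[2], W2)
  y <- array(0, c(H2, W2, d[3]))
  for (c in seq_len(d[3])) y[, , c] <- Ry %*% x[, , c] %*% t(Rx)
  y
}

nn_resize_bilinear_bwd <- function(dy, H1, W1, Ry, Rx) {
  d <- dim(dy)
  dx <- array(0, c(H1, W1, d[3]))
  for (c in seq_len(d[3])) dx[, , c] <- t(Ry) %*% dy[, , c] %*% Rx
  dx
}

nn_nearest_idx <- function(n_in, n_out) {
  pmin(pmax(floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1, 1), n_in)
}

nn_resize_nearest <- function(x, H2, W2) {
  iy <- nn_nearest_idx(dim(x)[1], H2)
  ix <- nn_nearest_idx(dim(x)[2], W2)
  if (length(dim(x)) == 2L) x[iy, ix, drop = FALSE] else x[iy, ix, , drop = FALSE]
}

# ---- softmax over the channel (last) dimension ----------------------------

nn_row_max <- function(z) {
  m <- z[, 1L]
  for (k in seq_len(ncol(z))[-1L]) m <- pmax(m, z[, k])
  m
}

nn_softmax_rows <- function(z) {
  z <- z - nn_row_max(z)
  e <- exp(z)
  e / rowSums(e)
}

nn_softmax_rows_bwd <- function(dp, p) {
  p * (dp - rowSums(dp * p))
}

# ---- scaled dot-product self-attention (single head) ----------------------

nn_attn_fwd <- function(X, Wq, Wk, Wv) {
  d <- ncol(Wq)
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  S <- tcrossprod(Q, K) / sqrt(d)
  A <- nn_softmax_rows(S)
  list(y = A %*% V, X = X, Q = Q, K = K, V = V, A = A, d = d)
}

nn_attn_bwd <- function(dy, cache, Wq, Wk, Wv) {
  A <- cache$A; V <- cache$V; Q <- cache$Q; K <- cache$K; X <- cache$X
  dA <- tcrossprod(dy, V)
  dV <- crossprod(A, dy)
  dS <- nn_softmax_rows_bwd(dA, A) / sqrt(cache$d)
  dQ <- dS %*% K
  dK <- crossprod(dS, Q)
  dX <- dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv)
  list(dX = dX,
       dWq = crossprod(X, dQ), dWk = crossprod(X, dK), dWv = crossprod(X, dV))
}

# ---- parameter init and SGD update ----------------------------------------

nn_he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

# global-norm gradient clipping
nn_clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (total > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}

# SGD with momentum and decoupled-from-bias weight decay. `opt` carries one
# velocity buffer per parameter.
nn_sgd_update <- function(params, grads, opt, lr, momentum, weight_decay) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && !grepl("_b$", nm)) g <- g + weight_decay * params[[nm]]
    v <- opt[[nm]]
    if (is.null(v)) v <- 0 * g
    v <- momentum * v - lr * g
    params[[nm]] <- params[[nm]] + v
    opt[[nm]] <- v
  }
  list(params = params, opt = opt)
}

nn_acc_grad <- function(grads, nm, g) {
  if (is.null(grads[[nm]])) grads[[nm]] <- g else grads[[nm]] <- grads[[nm]] + g
  grads
}

# 2x2 (or p x p) average pooling used to shrink attention token grids.
nn_avgpool_fwd <- function(x, p) {
  if (p <= 1L) return(list(y = x, p = p, dimx = dim(x)))
  d <- dim(x)
  Ho <- d[1] %/% p; Wo <- d[2] %/% p
  y <- array(0, c(Ho, Wo, d[3]))
  for (dy in seq_len(p)) for (dx in seq_len(p)) {
    y <- y + x[seq(dy, by = p, length.out = Ho),
               seq(dx, by = p, length.out = Wo), , drop = FALSE]
  }
  list(y = y / (p * p), p = p, dimx = d)
}

nn_avgpool_bwd <- function(dy, cache) {
  p <- cache$p
  if (p <= 1L) return(dy)
  d <- cache$dimx
  Ho <- dim(dy)[1]; Wo <- dim(dy)[2]
  dx <- array(0, d)
  g <- dy / (p * p)
  for (ddy in seq_len(p)) for (ddx in seq_len(p)) {
    dx[seq(ddy, by = p, length.out = Ho),
       seq(ddx, by = p, length.out = Wo), ] <- g
  }
  dx
}
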