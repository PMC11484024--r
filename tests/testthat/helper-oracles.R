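# Brute-force reference implementations used as independent oracles.
# All are deliberately written as plain loops over pixels/pairs, mirroring
# the defining formulas rather than the package's vectorised code paths.

# per-pixel three-branch thresholding rule
oracle_confidence <- function(Mhat, alpha, beta) {
  H <- dim(Mhat)[1]; W <- dim(Mhat)[2]; K <- dim(Mhat)[3] - 1L
  out <- matrix(255L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    fg <- Mhat[i, j, seq_len(K)]
    k <- which.max(fg)          # lowest index on ties
    m <- fg[k]
    out[i, j] <- if (m > beta) as.integer(k) else if (m < alpha) 0L else 255L
  }
  out
}

oracle_fuse <- function(p_r, p_crf) {
  out <- p_r
  for (i in seq_along(p_r))
    out[i] <- if (p_r[i] == p_crf[i]) p_r[i] else 255L
  out
}

# triple-loop confusion counts with ignore/exclusion semantics
oracle_confusion <- function(pred, gt, K, excluded = 0L) {
  classes <- setdiff(0:K, excluded)
  tp <- fp <- fn <- stats::setNames(integer(length(classes)),
                                    as.character(classes))
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
    g <- gt[i, j]
    if (g == 255L || g %in% excluded) next
    p <- pred[i, j]
    for (k in classes) {
      kk <- as.character(k)
      if (p == k && g == k) tp[kk] <- tp[kk] + 1L
      if (p == k && g != k) fp[kk] <- fp[kk] + 1L
      if (p != k && g == k) fn[kk] <- fn[kk] + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}

# double-loop masked cross-entropy that skips 255 pixels
oracle_masked_ce <- function(P, pseudo) {
  K <- dim(P)[3] - 1L
  total <- 0; nphi <- 0L
  for (i in seq_len(nrow(pseudo))) for (j in seq_len(ncol(pseudo))) {
    lab <- pseudo[i, j]
    if (lab == 255L) next
    ch <- if (lab == 0L) K + 1L else lab
    total <- total - log(P[i, j, ch])
    nphi <- nphi + 1L
  }
  if (nphi == 0L) 0 else total / nphi
}

# quadruple-loop dense pairwise energy (ordered pairs within radius)
oracle_energy <- function(P, image, S, cfg, normalize = TRUE) {
  if (max(image) > 1) image <- image / 255
  H <- dim(P)[1]; W <- dim(P)[2]; L <- dim(P)[3]
  r <- cfg$radius
  total <- 0
  for (i in seq_len(H)) for (j in seq_len(W)) for (a in seq_len(H))
    for (b in seq_len(W)) {
      if (i == a && j == b) next
      if (abs(i - a) > r || abs(j - b) > r) next
      G <- exp(-((i - a)^2 + (j - b)^2) / (2 * cfg$sigma_pos^2) -
                 sum((image[i, j, ] - image[a, b, ])^2) / (2 * cfg$sigma_rgb^2))
      e <- 0
      for (k1 in seq_len(L)) for (k2 in seq_len(L))
        if (k1 != k2) e <- e + P[i, j, k1] * P[a, b, k2]
      total <- total + S[i, j] * G * e
    }
  if (normalize) cfg$weight * total / (H * W) else total
}

# random probability array (per-pixel simplex over L channels)
random_simplex <- function(H, W, L) {
  P <- array(stats::runif(H * W * L), c(H, W, L))
  s <- array(rep(apply(P, c(1, 2), sum), L), c(H, W, L))
  P / s
}

random_label_map <- function(H, W, K, p255 = 0.2) {
  matrix(sample(c(0:K, 255L), H * W, replace = TRUE,
                prob = c(rep((1 - p255) / (K + 1), K + 1), p255)), H, W)
}

tiny_model <- function(K = 2, seed = 1, ...) {
  camseg_model(camseg_config(n_classes = K, channels = c(4L, 5L, 6L, 6L),
                             d = 3L, decoder_width = 4L, attn_pool = 1L,
                             seed = seed, ...))
}
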