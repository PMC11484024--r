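test_that("backbone feature maps satisfy the shape contract", {
  m <- camseg_model(camseg_config(n_classes = 3, seed = 0))
  x <- array(runif(64 * 64 * 3 * 8), c(64, 64, 3, 8))
  Fm <- extract_features(m, x)
  expect_equal(dim(Fm), c(16, 16, 48, 8))      # total stride 4
  # duplicate image in the batch -> identical features
  x[, , , 2] <- x[, , , 1]
  Fm <- extract_features(m, x)
  expect_equal(Fm[, , , 1], Fm[, , , 2], tolerance = 1e-12)
  # all-zero image stays finite
  expect_true(all(is.finite(extract_features(m, array(0, c(64, 64, 3, 1))))))
  # mixed sizes are rejected at batch assembly
  expect_error(camseg:::patches_to_batch(list(
    list(image = array(0, c(64, 64, 3))),
    list(image = array(0, c(32, 32, 3))))), "same size")
})

test_that("the activation layer maps C channels to K+1 and is deterministic", {
  m <- tiny_model(K = 3)
  Fm <- array(rnorm(16 * 16 * 6 * 2), c(16, 16, 6, 2))
  M1 <- discriminative_activation(m, Fm)
  expect_equal(dim(M1), c(16, 16, 4, 2))
  expect_identical(M1, discriminative_activation(m, Fm))
})

test_that("activation-layer weights receive nonzero gradient", {
  # finite differences on a scalar readout of the raw activation map
  m <- tiny_model(K = 2)
  Fm <- array(rnorm(8 * 8 * 6), c(8, 8, 6, 1))
  readout <- function(model) sum(discriminative_activation(model, Fm)^2)
  eps <- 1e-6
  seen_nonzero <- FALSE
  for (i in c(1, 5, 11)) {
    m2 <- m; m2$params$da_W[i] <- m2$params$da_W[i] + eps
    m3 <- m; m3$params$da_W[i] <- m3$params$da_W[i] - eps
    if (abs(readout(m2) - readout(m3)) / (2 * eps) > 1e-6) seen_nonzero <- TRUE
  }
  expect_true(seen_nonzero)
})

test_that("per-pixel normalisation reproduces hand-computed vectors", {
  # 3-4-5 identity and absolute-value handling of negative activations
  M <- array(c(3, 4), c(1, 1, 2))
  expect_equal(as.vector(normalize_activation(M)), c(0.6, 0.8))
  M2 <- array(c(-3, 4), c(1, 1, 2))
  expect_equal(as.vector(normalize_activation(M2)), c(0.6, 0.8))
})

test_that("normalised maps have unit per-pixel norm or are exactly zero", {
  set.seed(1)
  M <- array(rnorm(4 * 5 * 5), c(5, 5, 4))
  M[2, 3, ] <- 0                                # an all-zero pixel
  Mh <- normalize_activation(M)
  expect_true(all(Mh >= 0 & Mh <= 1))
  for (i in 1:5) for (j in 1:5) {
    n <- sqrt(sum(Mh[i, j, ]^2))
    if (i == 2 && j == 3) expect_identical(n, 0) else
      expect_lt(abs(n - 1), 1e-5)
  }
})

test_that("class gating obeys identity, null and elementwise-product rules", {
  set.seed(2)
  Fm <- array(rnorm(6 * 6 * 5 * 2), c(6, 6, 5, 2))
  ones <- array(1, c(6, 6, 3, 2)); zeros <- array(0, c(6, 6, 3, 2))
  expect_equal(class_features(Fm, ones)[[1]], Fm)
  expect_equal(class_features(Fm, zeros)[[2]], array(0, dim(Fm)))
  Mh <- array(runif(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  got <- class_features(Fm, Mh)
  for (k in 1:2) for (b in 1:2) for (cc in 1:5) for (i in 1:6) for (j in 1:6)
    expect_equal(got[[k]][i, j, cc, b], Fm[i, j, cc, b] * Mh[i, j, k, b])
  expect_error(class_features(Fm, array(1, c(3, 3, 3, 2))), "aligned")
})

test_that("uniform attention reduces to the residual plus mean-mixed projection", {
  m <- tiny_model(K = 1, seed = 4)
  m$params$attn_Wq[] <- 0                  # forces uniform attention weights
  Fk <- array(rnorm(2 * 2 * 6), c(2, 2, 6, 1))
  A <- self_attention_pool(m, Fk)
  X <- matrix(Fk, 4, 6)
  proj <- sweep(X %*% m$params$proj_W, 2, m$params$proj_b, `+`)
  V <- proj %*% m$params$attn_Wv
  expect_A <- proj + matrix(colMeans(V), 4, 3, byrow = TRUE)
  expect_equal(array(A, c(4, 3)), unname(expect_A), tolerance = 1e-10)
})

test_that("batch attention is equivariant to image order and symmetric for duplicates", {
  m <- tiny_model(K = 1, seed = 5)
  set.seed(6)
  Fk <- array(rnorm(4 * 4 * 6 * 3), c(4, 4, 6, 3))
  A <- self_attention_pool(m, Fk)
  perm <- c(3, 1, 2)
  Ap <- self_attention_pool(m, Fk[, , , perm, drop = FALSE])
  expect_equal(Ap, A[, , , perm, drop = FALSE], tolerance = 1e-10)
  Fk[, , , 2] <- Fk[, , , 1]
  Ad <- self_attention_pool(m, Fk)
  expect_equal(Ad[, , , 1], Ad[, , , 2], tolerance = 1e-10)
})

test_that("classification scores are GAP plus an affine head", {
  m <- tiny_model(K = 2, seed = 7)
  d <- m$config$d
  hk <- function(k) min(k, ncol(m$params$head_W))  # shared or per-class head
  # spatially constant attended map: GAP returns the constant vector
  A1 <- array(rep(1:3, each = 4), c(2, 2, d, 1))
  lg1 <- classification_scores(m, list(A1, A1))
  hw <- c(1, 2, 3)
  for (k in 1:2)
    expect_equal(lg1[1, k],
                 sum(hw * m$params$head_W[, hk(k)]) + m$params$head_b[hk(k)])
  # linearity of pooling: doubling A doubles the logit minus the bias
  lg2 <- classification_scores(m, list(2 * A1, 2 * A1))
  b <- vapply(1:2, function(k) m$params$head_b[hk(k)], numeric(1))
  expect_equal(as.vector(lg2), as.vector(2 * lg1) - b, tolerance = 1e-10)
  # closed-form check on a 1 x 1 spatial map
  a <- array(rnorm(d), c(1, 1, d, 1))
  lg <- classification_scores(m, list(a, a))
  for (k in 1:2)
    expect_equal(lg[1, k], sum(as.vector(a) * m$params$head_W[, hk(k)]) +
                   m$params$head_b[hk(k)])
})

test_that("classification loss is mean BCE with the expected closed forms", {
  # zero logits -> ln 2
  expect_equal(classification_loss(matrix(0, 3, 2), matrix(0, 3, 2)), log(2),
               tolerance = 1e-6)
  # saturated correct logits -> loss ~ 0
  lab <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_lt(classification_loss((2 * lab - 1) * 50, lab), 1e-6)
  # brute-force per-element BCE average
  set.seed(8)
  z <- matrix(rnorm(6), 2, 3); y <- matrix(rbinom(6, 1, 0.5), 2, 3)
  ref <- 0
  for (i in 1:2) for (k in 1:3) {
    p <- 1 / (1 + exp(-z[i, k]))
    ref <- ref - (y[i, k] * log(p) + (1 - y[i, k]) * log(1 - p)) / 6
  }
  expect_equal(classification_loss(z, y), ref, tolerance = 1e-10)
  expect_error(classification_loss(z, y + 0.5), "binary")
})

test_that("every parameter gradient of the joint step matches finite differences", {
  m <- tiny_model(K = 2, seed = 3)
  set.seed(5)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  labels <- matrix(c(1, 0, 0, 1), 2, 2)
  pseudo <- array(sample(c(0:2, 255L), 16 * 16 * 2, replace = TRUE),
                  c(16, 16, 2))
  cfg <- train_config(lambda = 0.7, crop_size = 16L, scale_range = c(1, 1),
                      energy = energy_config(radius = 2L))
  S <- list(matrix(runif(256), 16, 16), matrix(runif(256), 16, 16))
  res <- camseg:::joint_forward_backward(m, x, labels, pseudo, cfg,
                                         fixed_S = S)
  lossfn <- function(model)
    camseg:::joint_forward_backward(model, x, labels, pseudo, cfg,
                                    fixed_S = S)$report$L_total
  eps <- 1e-6
  for (nm in names(res$grads)) {
    g <- res$grads[[nm]]
    i <- sample(length(g), 1)
    m2 <- m; m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
    m3 <- m; m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
    num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
    expect_lt(abs(num - g[i]) / max(1e-4, abs(num) + abs(g[i])), 1e-3)
  }
})
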