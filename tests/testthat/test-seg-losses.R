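test_that("segmentation forward returns per-pixel simplices at image size", {
  m <- tiny_model(K = 2, seed = 9)
  for (sz in c(64, 96)) {
    x <- array(runif(sz * sz * 3), c(sz, sz, 3, 1))
    Fm <- extract_features(m, x)
    P <- seg_forward(m, Fm, c(sz, sz))
    expect_equal(dim(P), c(sz, sz, 3, 1))
    sums <- apply(P, c(1, 2, 4), sum)
    expect_lt(max(abs(sums - 1)), 1e-5)
    expect_true(all(P >= 0 & P <= 1))
    expect_identical(P, seg_forward(m, Fm, c(sz, sz)))
  }
})

test_that("masked cross-entropy obeys its closed forms and oracle", {
  set.seed(20)
  P <- random_simplex(8, 8, 4)
  # fully ignored map -> zero loss
  expect_identical(masked_cross_entropy(P, matrix(255L, 8, 8)), 0)
  # single confident pixel with P = 0.5 at its label -> ln 2
  P1 <- random_simplex(3, 3, 3)
  P1[2, 2, ] <- c(0.5, 0.3, 0.2)
  ps <- matrix(255L, 3, 3); ps[2, 2] <- 1L
  expect_equal(masked_cross_entropy(P1, ps), log(2), tolerance = 1e-6)
  # random case vs the double-loop oracle (255 pixels skipped)
  for (rep in 1:10) {
    P <- random_simplex(8, 8, 4)
    pseudo <- random_label_map(8, 8, 3)
    expect_equal(masked_cross_entropy(P, pseudo), oracle_masked_ce(P, pseudo),
                 tolerance = 1e-12)
  }
  # with all pixels confident it is the standard cross-entropy
  pseudo <- matrix(sample(0:3, 64, TRUE), 8, 8)
  expect_equal(masked_cross_entropy(P, pseudo), oracle_masked_ce(P, pseudo),
               tolerance = 1e-12)
  expect_error(masked_cross_entropy(P, matrix(7L, 8, 8)), "outside")
})

test_that("soft filter is 1 - max P on confident pixels and 1 elsewhere", {
  P <- random_simplex(4, 4, 4)
  P[1, 1, ] <- c(1, 0, 0, 0)
  P[2, 2, ] <- rep(0.25, 4)
  phi <- matrix(FALSE, 4, 4); phi[1, 1] <- TRUE; phi[2, 2] <- TRUE
  S <- soft_filter(P, phi)
  expect_equal(S[1, 1], 0)
  expect_equal(S[2, 2], 0.75)
  expect_true(all(S[!phi] == 1))
  expect_true(all(S >= 0 & S <= 1))
})

test_that("dense energy vanishes for a constant one-hot prediction", {
  P <- array(0, c(6, 6, 3)); P[, , 2] <- 1
  img <- array(runif(6 * 6 * 3), c(6, 6, 3))
  expect_equal(dense_energy_loss(P, img), 0)
})

test_that("the two-pixel hand computation gives 2g for ordered pairs", {
  P <- array(c(1, 0, 0, 1), c(1, 2, 2))     # pixel 1 class 1, pixel 2 class 2
  img <- array(0.5, c(1, 2, 3))             # identical colours
  g <- exp(-1 / (2 * 36))                   # sigma_pos = 6, distance 1
  got <- dense_energy_loss(P, img, matrix(1, 1, 2), energy_config(),
                           normalize = FALSE)
  expect_equal(got, 2 * g, tolerance = 1e-12)
})

test_that("dense energy matches the quadruple-loop oracle on 12x12 inputs", {
  set.seed(21)
  cfg <- energy_config(sigma_pos = 3, sigma_rgb = 0.2, radius = 3)
  for (rep in 1:3) {
    P <- random_simplex(12, 12, 3)
    img <- array(runif(12 * 12 * 3), c(12, 12, 3))
    S <- matrix(runif(144), 12, 12)
    expect_equal(dense_energy_loss(P, img, S, cfg),
                 oracle_energy(P, img, S, cfg), tolerance = 1e-5)
  }
})

test_that("agreeing neighbours strictly lower the pairwise energy", {
  img <- array(0.3, c(1, 2, 3))
  S <- matrix(1, 1, 2)
  vals <- vapply(seq(0.1, 0.9, by = 0.2), function(p2a) {
    P <- array(c(1, 0, 0, p2a, 1 - p2a, 0), c(1, 2, 3))
    P[1, 1, ] <- c(1, 0, 0); P[1, 2, ] <- c(p2a, 1 - p2a, 0)
    dense_energy_loss(P, img, S, energy_config())
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("radius truncation converges monotonically to the full sum", {
  set.seed(22)
  cfg0 <- energy_config(sigma_pos = 1.5)
  P <- random_simplex(16, 16, 3)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  S <- matrix(runif(256), 16, 16)
  raw <- vapply(c(1, 2, 4, 6, 15), function(r)
    dense_energy_loss(P, img, S, energy_config(sigma_pos = 1.5, radius = r),
                      normalize = FALSE), numeric(1))
  expect_true(all(diff(raw) >= 0))
  # radius >= 4 sigma_pos captures the full sum to within 1%
  expect_lt(abs(raw[4] - raw[5]) / raw[5], 0.01)
})

test_that("loss composition identities hold", {
  expect_identical(segmentation_loss(0, 0), 0)
  expect_identical(segmentation_loss(0.3, 0.2), 0.5)
  set.seed(23)
  P <- random_simplex(8, 8, 3)
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  pseudo <- random_label_map(8, 8, 2)
  ce <- masked_cross_entropy(P, pseudo)
  en <- dense_energy_loss(P, img, soft_filter(P, pseudo != 255L))
  rep <- loss_report(L_class = 0.4, L_ce = ce, L_energy = en, lambda = 0.5)
  expect_equal(rep$L_seg, ce + en, tolerance = 1e-6)
  expect_equal(rep$L_total, 0.4 + 0.5 * (ce + en), tolerance = 1e-6)
  expect_true(ce >= 0 && en >= 0)
})
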