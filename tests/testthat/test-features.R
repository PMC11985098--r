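ks3 <- kernel_spec("matern52", 0.5, 3)

test_that("basis construction: dimensions, determinism, frequency law", {
  b <- build_basis(3, 2, 2, ks3, seed = 1)
  expect_equal(b$D, 3 * 2 + 3 * 4)
  expect_equal(length(b$blocks), 6)
  expect_true(all(b$phase >= 0 & b$phase < 2 * pi))
  b2 <- build_basis(3, 2, 2, ks3, seed = 1)
  expect_identical(b$omega, b2$omega)
  expect_identical(b$phase, b2$phase)
  ## sampled frequencies follow the coordinate's spectral law (KS at 1%)
  bb <- build_basis(1, 1e4, 1, kernel_spec("matern52", 0.5, 1), seed = 5)
  ksp <- suppressWarnings(ks.test(bb$omega[1, ], function(q)
    spectral_cdf(kernel_spec("matern52", 0.5, 1), 1, q)))
  expect_gt(ksp$p.value, 0.01)
  expect_error(build_basis(3, 2, 4, ks3, seed = 1), "r must")
})

test_that("univariate features and their analytic derivatives", {
  b <- build_basis(3, 40, 2, ks3, seed = 2)
  expect_true(all(abs(phi(b, 1, 0.3)) <= sqrt(2 / 40) + 1e-12))
  h <- 1e-6; t0 <- 0.37
  expect_equal(phi(b, 2, t0, 1),
               (phi(b, 2, t0 + h) - phi(b, 2, t0 - h)) / (2 * h),
               tolerance = 1e-5)
  expect_equal(phi(b, 2, t0, 2),
               (phi(b, 2, t0 + h, 1) - phi(b, 2, t0 - h, 1)) / (2 * h),
               tolerance = 1e-5)
  ## a zero frequency gives a constant feature with zero derivative
  bz <- b; bz$omega[1, 1] <- 0
  expect_equal(phi(bz, 1, 0.5, 1)[1], 0)
  bl <- build_basis(2, 3, 1, kernel_spec("laplacian", 1, 2), seed = 1)
  expect_error(phi(bl, 1, 0.5, 1), "differentiable")
})

test_that("ANOVA feature vectors: structure, block zeros, derivatives", {
  ks2 <- kernel_spec("matern52", 0.5, 2)
  b1 <- build_basis(2, 1, 2, ks2, seed = 3)
  v <- anova_features(b1, c(0.2, 0.8))
  expect_length(v, 3)
  expect_equal(v[3], v[1] * v[2])
  ## derivative in a coordinate a block lacks annihilates that block
  b3 <- build_basis(3, 3, 3, ks3, seed = 4)
  v1 <- anova_features(b3, c(0.1, 0.5, 0.9), 1L)
  blk23 <- which(vapply(b3$blocks, function(B) identical(B, c(2L, 3L)), TRUE))
  idx <- b3$offsets[blk23] + seq_len(b3$block_sizes[blk23])
  expect_equal(v1[idx], rep(0, 9))
  ## directional finite difference matches the analytic derivative vector
  h <- 1e-5; tp <- c(0.2, 0.6, 0.8)
  fd <- (anova_features(b3, tp + c(0, h, 0)) -
         anova_features(b3, tp - c(0, h, 0))) / (2 * h)
  expect_equal(fd, anova_features(b3, tp, 2L), tolerance = 1e-5)
  expect_error(anova_features(b3, tp, 5L), "outside")
})

test_that("derivative annihilation pattern is exact for d = 4, r = 3", {
  ks4 <- kernel_spec("gaussian", 0.8, 4)
  b4 <- build_basis(4, 2, 3, ks4, seed = 6)
  tp <- runif(4)
  for (j in 1:4) {
    v <- anova_features(b4, tp, j)
    for (bi in seq_along(b4$blocks)) {
      idx <- b4$offsets[bi] + seq_len(b4$block_sizes[bi])
      if (j %in% b4$blocks[[bi]]) {
        expect_gt(max(abs(v[idx])), 0)
      } else {
        expect_equal(v[idx], rep(0, length(idx)))
      }
    }
  }
})

test_that("augmented rows stack channel blocks and differentiate the model", {
  b3 <- build_basis(3, 3, 3, ks3, seed = 7)
  tp <- c(0.3, 0.6, 0.2); p <- 2
  expect_equal(augmented_row(b3, tp, 0L, 0L), anova_features(b3, tp))
  expect_length(augmented_row(b3, tp, p, 0L), (p + 1) * b3$D)
  expect_length(augmented_row(b3, tp, p, 2L), (p + 1) * b3$D)
  expect_error(augmented_row(b3, tp, p, 3L), "kind")
  set.seed(1); cc <- rnorm((p + 1) * b3$D)
  f <- function(t) sum(augmented_row(b3, t, p, 0L) * cc)
  h <- 1e-5
  fd <- (f(tp + c(0, h, 0)) - f(tp - c(0, h, 0))) / (2 * h)
  expect_equal(fd, sum(augmented_row(b3, tp, p, 2L) * cc), tolerance = 1e-5)
})

test_that("factorized Gram equals brute-force row inner products", {
  b <- build_basis(3, 3, 2, ks3, seed = 8)
  set.seed(9)
  T <- matrix(runif(18), 6, 3); kinds <- c(0L, 1L, 2L, 0L, 2L, 1L); p <- 2
  X <- t(sapply(1:6, function(i) augmented_row(b, T[i, ], p, kinds[i])))
  G <- factorized_gram(b, T, kinds, p)
  expect_equal(G, tcrossprod(X), tolerance = 1e-10)
  expect_equal(G, t(G))
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  ## the explicit design matrix agrees row by row as well
  expect_equal(gradspline:::.design_matrix(b, T, kinds, p), X,
               tolerance = 1e-12)
})

test_that("averaged feature inner products reconstruct the kernel", {
  ## E <phi(t), phi(t')> = K(t - t'): average over seeded bases
  ks1 <- kernel_spec("matern52", 0.5, 1)
  us <- c(0.1, 0.3, 0.6, 1.0, 1.6)
  nb <- 200; s <- 500
  vals <- matrix(0, nb, length(us))
  for (i in seq_len(nb)) {
    b <- build_basis(1, s, 1, ks1, seed = 1000 + i)
    for (k in seq_along(us))
      vals[i, k] <- sum(phi(b, 1, 0.1) * phi(b, 1, 0.1 + us[k]))
  }
  for (k in seq_along(us)) {
    se <- sd(vals[, k]) / sqrt(nb)
    expect_lt(abs(mean(vals[, k]) - kernel_eval(ks1, 1, us[k])), 3 * se + 1e-12)
  }
})

test_that("basis JSON round trip reproduces features exactly", {
  b <- build_basis(2, 4, 2, kernel_spec("gaussian", 0.9, 2), seed = 10)
  f <- tempfile(fileext = ".json")
  basis_to_json(b, f)
  b2 <- basis_from_json(f)
  tp <- c(0.4, 0.7)
  expect_equal(anova_features(b2, tp), anova_features(b, tp))
  unlink(f)
})
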