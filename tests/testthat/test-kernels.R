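test_that("univariate kernels follow the K(0) = 1 convention and symmetry", {
  for (fam in c("matern52", "gaussian", "laplacian", "cauchy")) {
    ks <- kernel_spec(fam, scales = c(0.4, 1.3), d = 2)
    expect_equal(kernel_eval(ks, 1, 0), 1)
    expect_equal(kernel_eval(ks, 2, 0), 1)
    u <- c(0.17, 0.9, 2.4)
    expect_equal(kernel_eval(ks, 1, u), kernel_eval(ks, 1, -u))
  }
  ## printed Matern form at tau = 1, u = 1
  ks1 <- kernel_spec("matern52", 1, 1)
  expect_equal(kernel_eval(ks1, 1, 1), (7 / 3) * exp(-1))
  expect_error(kernel_spec("matern52", scales = -1), "scales")
})

test_that("tensor-product kernel multiplies coordinate factors", {
  ks <- kernel_spec("matern52", 1, 2)
  expect_equal(product_kernel_eval(ks, c(0.3, 0.7), c(0.3, 0.7)), 1)
  expect_equal(product_kernel_eval(ks, c(1, 2), c(0, 1)),
               ((7 / 3) * exp(-1))^2)
  ks1 <- kernel_spec("cauchy", 0.8, 1)
  expect_equal(product_kernel_eval(ks1, 0.9, 0.2),
               kernel_eval(ks1, 1, 0.7))
  expect_error(product_kernel_eval(ks, c(1, 2, 3), c(0, 1)), "length")
})

test_that("mixed kernel partials match finite differences and spectral moments", {
  h <- 1e-5
  for (fam in c("matern52", "gaussian", "cauchy")) {
    ks <- kernel_spec(fam, c(0.4, 0.6, 0.8), 3)
    set.seed(5)
    for (rep in 1:3) {
      t1 <- runif(3); t2 <- runif(3)
      ## zeroth order equals plain evaluation
      expect_equal(product_kernel_partial(ks, t1, t2),
                   product_kernel_eval(ks, t1, t2))
      an <- product_kernel_partial(ks, t1, t2, c(1, 0, 0), c(0, 1, 0))
      fd <- (product_kernel_partial(ks, t1 + c(h, 0, 0), t2, order2 = c(0, 1, 0)) -
             product_kernel_partial(ks, t1 - c(h, 0, 0), t2, order2 = c(0, 1, 0))) /
            (2 * h)
      expect_equal(an, fd, tolerance = 1e-5)
    }
  }
  ## gaussian with unit spectral variance: mixed second at zero displacement
  kg <- kernel_spec("gaussian", 1, 1)
  expect_equal(product_kernel_partial(kg, 0.3, 0.3, 1, 1), 1)
  kl <- kernel_spec("laplacian", 1, 1)
  expect_error(product_kernel_partial(kl, 0.1, 0.5, 1, 0), "differentiable")
})

test_that("spectral sampling is seeded, normalized, and moment-correct", {
  ks <- kernel_spec("gaussian", 0.7, 1)
  expect_identical(spectral_sample(ks, 1, 50, seed = 3),
                   spectral_sample(ks, 1, 50, seed = 3))
  w <- spectral_sample(ks, 1, 1e5, seed = 11)
  ## sample variance of the gaussian spectral law (sd = tau) within 3 MC SEs
  se <- 0.7^2 * sqrt(2 / (1e5 - 1))
  expect_lt(abs(var(w) - 0.7^2), 3 * se)
  ## densities integrate to one over [-50/tau, 50/tau] (light-tailed families)
  for (fam in c("gaussian", "matern52", "cauchy")) {
    for (tau in c(0.5, 1)) {
      ksf <- kernel_spec(fam, tau, 1)
      q <- integrate(function(x) spectral_density(ksf, 1, x),
                     -50 / tau, 50 / tau, rel.tol = 1e-9)
      expect_equal(q$value, 1, tolerance = 1e-4)
    }
  }
  ## the laplacian kernel's Cauchy spectral law is heavy-tailed: compare the
  ## truncated integral with the analytic Cauchy mass instead
  kl <- kernel_spec("laplacian", 1, 1)
  q <- integrate(function(x) spectral_density(kl, 1, x), -50, 50)
  expect_equal(q$value, spectral_cdf(kl, 1, 50) - spectral_cdf(kl, 1, -50),
               tolerance = 1e-6)
})

test_that("Bochner pairing: Monte Carlo cosine averages reproduce each kernel", {
  ## strict three-standard-error check for the differentiable workhorses,
  ## a looser five-SE sanity bound for the heavy-tailed pairings
  for (fam in c("gaussian", "matern52", "cauchy", "laplacian")) {
    mult <- if (fam %in% c("gaussian", "matern52")) 3 else 5
    ks <- kernel_spec(fam, 0.7, 1)
    w <- spectral_sample(ks, 1, 1e5, seed = 42)
    for (u in c(0.1, 0.35, 0.8, 1.5, 3)) {
      cw <- cos(w * u)
      se <- sd(cw) / sqrt(length(w))
      expect_lt(abs(mean(cw) - kernel_eval(ks, 1, u)), mult * se + 1e-12)
    }
  }
})

test_that("product-kernel Gram matrices are positive semidefinite", {
  set.seed(8)
  for (fam in c("matern52", "gaussian", "cauchy", "laplacian")) {
    ks <- kernel_spec(fam, c(0.5, 0.9, 0.6), 3)
    T <- matrix(runif(24), 8, 3)
    G <- outer(seq_len(8), seq_len(8),
               Vectorize(function(i, j) product_kernel_eval(ks, T[i, ], T[j, ])))
    expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})
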