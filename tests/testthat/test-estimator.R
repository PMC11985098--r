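test_that("gradient_data enforces its invariants", {
  T0 <- matrix(runif(30), 10, 3)
  expect_error(gradient_data(list(T0), list(rnorm(9))), "length")
  expect_error(gradient_data(list(T0 + 2), list(rnorm(10))), "outside")
  expect_error(gradient_data(rep(list(T0), 5), rep(list(rnorm(10)), 5)),
               "p must be")
  d <- gradient_data(list(T0), list(rnorm(10)))
  expect_equal(d$p, 0L)
  expect_equal(d$n, 10L)
})

test_that("channel weights: known variances, empty case, difference estimator", {
  T0 <- matrix(runif(30), 10, 3)
  dat <- gradient_data(rep(list(T0), 2), list(rnorm(10), rnorm(10)),
                       sigma2 = c(1, 4))
  expect_equal(estimate_weights(dat), 0.25)
  expect_length(estimate_weights(gradient_data(list(T0), list(rnorm(10)))), 0)
  ## equal-noise channels on a nearly flat truth: estimated ratios near one
  n <- 500; inside <- 0
  reps <- 100
  for (i in seq_len(reps)) {
    set.seed(3000 + i)
    des <- lapply(1:3, function(k) matrix(runif(n * 3, 0.5, 1.5), n, 3))
    resp <- lapply(1:3, function(k)
      0.05 * rowSums(des[[k]]) + rnorm(n, 0, 0.35))
    dat <- gradient_data(des, resp, domain = rbind(rep(0.5, 3), rep(1.5, 3)))
    w <- estimate_weights(dat)
    inside <- inside + all(w >= 0.7 & w <= 1.4)
  }
  expect_gte(inside / reps, 0.9)
})

test_that("assemble_system stacks channels with the documented row weights", {
  dat <- cd_simulate(12, 0, seed = 2, p = 2)
  b <- build_basis(3, 3, 3, kernel_spec("matern52", 0.5, 3), seed = 1)
  sys <- assemble_system(dat, b, estimate_weights(dat))
  expect_equal(sys$N, 36)
  expect_equal(sys$z, as.numeric(sys$kinds == 0))
  expect_equal(unique(sys$v[sys$kinds == 0]), 1 / 12)
  ## rows reproduce augmented_row output
  X <- gradspline:::.design_matrix(b, sys$T, sys$kinds, 2)
  i <- c(1, 15, 30)
  for (u in i)
    expect_equal(X[u, ], augmented_row(b, sys$T[u, ], 2, sys$kinds[u]),
                 tolerance = 1e-12)
  ## p = 0: plain features only
  dat0 <- cd_simulate(12, 0, seed = 2, p = 0)
  sys0 <- assemble_system(dat0, b, numeric(0))
  expect_equal(sys0$N, 12)
  expect_equal(sys0$D_total, b$D)
})

test_that("ridge solves: shrinkage limit, primal/dual agreement, span recovery", {
  dat <- cd_simulate(25, 0, seed = 5, p = 2)
  b <- build_basis(3, 4, 3, kernel_spec("matern52", 0.5, 3), seed = 3)
  sys <- assemble_system(dat, b, c(1, 1))
  ## enormous penalty: coefficients vanish, intercept = mean of channel 0
  fb <- ridge_fit(sys, 1e8)
  expect_lt(sqrt(sum(fb$coef^2)), 1e-6)
  expect_equal(fb$intercept, mean(dat$responses[[1]]), tolerance = 1e-6)
  ## primal and dual produce the same solution
  fp <- ridge_fit(sys, 0.01, method = "primal")
  fd <- ridge_fit(sys, 0.01, method = "dual")
  cd <- gradspline:::.dual_to_coef(b, sys$T, sys$kinds, 2, fd$gamma)
  expect_equal(cd, fp$coef, tolerance = 1e-8)
  expect_equal(fd$intercept, fp$intercept, tolerance = 1e-8)
  expect_equal(fd$fitted, fp$fitted, tolerance = 1e-8)
  ## noiseless in-span responses are recovered at tiny penalty (ridge bias
  ## on the smallest Gram modes caps accuracy at about sqrt(lambda) per
  ## unit response, so the instance keeps responses of order one)
  bs <- build_basis(2, 3, 1, kernel_spec("matern52", 0.4, 2), seed = 3)
  span <- in_span_data(bs, p = 2, n0 = 40, seed = 7, sd = 0.02)
  sys2 <- assemble_system(span$data, bs, c(1, 1))
  f0 <- ridge_fit(sys2, 1e-10)
  expect_lt(sqrt(sum((sys2$y - f0$fitted)^2)), 1e-6)
})

test_that("GCV: influence identity, trace monotonicity, degenerate grid", {
  dat <- cd_simulate(20, 0, seed = 6, p = 2)
  b <- build_basis(3, 3, 3, kernel_spec("matern52", 0.5, 3), seed = 4)
  sys <- assemble_system(dat, b, c(1, 1))
  grid <- c(1e-3, 1e-2, 1)
  g <- gcv_select(sys, grid)
  for (lam in grid) {
    rf <- ridge_fit(sys, lam)
    ev <- gradspline:::.gcv_eval(g$factor, sys, lam)
    expect_lt(max(abs(rf$fitted - ev$yhat)), 1e-8)
  }
  expect_true(all(diff(g$trace) < 0))
  g1 <- gcv_select(sys, 0.05)
  expect_equal(g1$lambda, 0.05)
})

test_that("fitting is deterministic and predictions match the feature model", {
  dat <- cd_simulate(30, 0, seed = 7, p = 2)
  f1 <- gradspline(dat, scales = 0.5, seed = 11)
  f2 <- gradspline(dat, scales = 0.5, seed = 11)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$lambda, f2$lambda)
  set.seed(8); tp <- matrix(runif(30, 0.5, 1.5), 10, 3)
  manual <- vapply(1:10, function(i) {
    Tu <- gradspline:::.to_unit(tp[i, , drop = FALSE], dat$domain)
    sum(augmented_row(f1$basis, drop(Tu), 2, 0L) * f1$coefficients) +
      f1$intercept
  }, numeric(1))
  expect_equal(predict(f1, tp), manual, tolerance = 1e-10)
  ## analytic gradient prediction vs central differences, any coordinate
  h <- 1e-4
  for (j in c(1, 3)) {
    fdp <- (predict(f1, fd_shift(tp, j, h)) -
            predict(f1, fd_shift(tp, j, -h))) / (2 * h)
    expect_equal(predict(f1, tp, gradient = j), fdp, tolerance = 1e-4)
  }
  ## p = 0 predictions depend only on the c0 block
  dat0 <- cd_simulate(30, 0, seed = 7, p = 0)
  f0 <- gradspline(dat0, scales = 0.5, seed = 11)
  expect_length(f0$coefficients, f0$basis$D)
})

test_that("noiseless additive truth is recovered accurately", {
  tr <- truth_additive(3)
  dat <- ssanova_synthetic(tr, 200, 3, 3, error_model(sigma = 0), seed = 13)
  ft <- gradspline(dat, scales = 0.5, r = 1, s = 50, seed = 14)
  set.seed(15); U <- matrix(runif(3000), 1000, 3)
  expect_lt(mean((predict(ft, U) - truth_eval(tr, U))^2), 1e-3)
})

test_that("fitted models serialize to JSON and replay exactly", {
  dat <- cd_simulate(20, 0, seed = 9, p = 2)
  ft <- gradspline(dat, scales = 0.5, seed = 21)
  f <- tempfile(fileext = ".json")
  write_gradspline(ft, f)
  ft2 <- read_gradspline(f)
  set.seed(10); tp <- matrix(runif(15, 0.5, 1.5), 5, 3)
  expect_equal(predict(ft2, tp), predict(ft, tp), tolerance = 1e-10)
  expect_equal(predict(ft2, tp, gradient = 2), predict(ft, tp, gradient = 2),
               tolerance = 1e-10)
  unlink(f)
})

test_that("laplacian kernel is usable for p = 0 only", {
  T0 <- matrix(runif(60), 20, 3)
  y0 <- sin(2 * pi * T0[, 1]) + rnorm(20, 0, 0.1)
  dat0 <- gradient_data(list(T0), list(y0))
  ft <- gradspline(dat0, kernel = "laplacian", scales = 0.5, s = 5, seed = 1)
  expect_true(is.finite(predict(ft, T0[1, , drop = FALSE])))
  dat2 <- cd_simulate(10, 0, seed = 1, p = 1)
  expect_error(gradspline(dat2, kernel = "laplacian", scales = 0.5, seed = 1),
               "differentiable")
})
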