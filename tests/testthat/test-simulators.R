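test_that("option value closed form: asymptote, monotonicity, degenerate noise", {
  ## deep in the money: value approaches S0 - 100 e^{-r}
  expect_equal(bs_true_f0(1e4, 0.03, 0.5), 1e4 - 100 * exp(-0.03),
               tolerance = 1e-3)
  S0s <- seq(80, 120, length.out = 21)
  expect_true(all(diff(bs_true_f0(S0s, 0.03, 0.5)) > 0))
  expect_error(bs_true_f0(100, 0.03, 0), "positive")
  ## vanishing volatility: payoffs become deterministic
  dat <- bs_simulate(bs_config(k = 2, q = 20), seed = 1, p = 0)
  ## (use the simulator formulas directly at sigma -> 0)
  S0 <- 110; r <- 0.05; sg <- 1e-8
  set.seed(1); w <- rnorm(20)
  ST <- S0 * exp((r - sg^2 / 2) + sg * w)
  expect_equal(exp(-r) * pmax(ST - 100, 0),
               rep(exp(-r) * (S0 * exp(r) - 100), 20), tolerance = 1e-6)
})

test_that("Monte Carlo validates lognormal mean, price, and IPA gradients", {
  set.seed(2); n <- 1e6
  S0 <- 100; r <- 0.03; sg <- 0.5
  w <- rnorm(n); ST <- S0 * exp((r - sg^2 / 2) + sg * w)
  expect_lt(abs(mean(ST) - S0 * exp(r)), 3 * sd(ST) / sqrt(n))
  pay <- exp(-r) * pmax(ST - 100, 0)
  expect_lt(abs(mean(pay) - bs_true_f0(S0, r, sg)), 3 * sd(pay) / sqrt(n))
  itm <- ST >= 100
  ipa <- list(exp(-r) * (ST / S0) * itm,
              -pay + exp(-r) * ST * itm,
              exp(-r) * (1 / sg) * (log(ST / S0) - (r + sg^2 / 2)) * ST * itm)
  h <- c(0.1, 1e-5, 1e-5)
  fd <- c((bs_true_f0(S0 + h[1], r, sg) - bs_true_f0(S0 - h[1], r, sg)) / (2 * h[1]),
          (bs_true_f0(S0, r + h[2], sg) - bs_true_f0(S0, r - h[2], sg)) / (2 * h[2]),
          (bs_true_f0(S0, r, sg + h[3]) - bs_true_f0(S0, r, sg - h[3])) / (2 * h[3]))
  for (j in 1:3)
    expect_lt(abs(mean(ipa[[j]]) - fd[j]), 3 * sd(ipa[[j]]) / sqrt(n))
})

test_that("option simulator returns a valid dataset with variance records", {
  dat <- bs_simulate(bs_config(k = 3, q = 50), seed = 3, p = 3)
  expect_s3_class(dat, "gradient_data")
  expect_equal(dat$n, rep(27L, 4))
  expect_length(dat$sigma2, 4)
  expect_length(attr(dat, "pointvar")[[1]], 27)
  ## grid includes the box endpoints
  expect_true(all(c(80, 120) %in% dat$designs[[1]][, 1]))
})

test_that("Cobb-Douglas truth: homogeneity, printed value, analytic gradient", {
  cfg <- cd_config()
  t0 <- c(0.8, 1.2, 0.9, 1.1)
  expect_equal(cd_true_f0(c(2 * t0[1:3], t0[4]), cfg), 2 * cd_true_f0(t0, cfg),
               tolerance = 1e-10)
  cs <- 2.1
  expect_equal(cd_true_f0(rep(1, 4), cfg),
               prod((cs / c(0.8, 0.7, 0.6))^(c(0.8, 0.7, 0.6) / cs)))
  h <- 1e-6
  for (j in 1:4) {
    e <- h * (1:4 == j)
    fd <- (cd_true_f0(t0 + e, cfg) - cd_true_f0(t0 - e, cfg)) / (2 * h)
    expect_equal(cd_gradient(t0, j, cfg), fd, tolerance = 1e-6)
  }
  expect_error(cd_true_f0(c(-1, 1, 1, 1), cfg), "positive")
})

test_that("Cobb-Douglas simulator: noiseless exactness and noise law", {
  cfg0 <- cd_config(sd = 0)
  d0 <- cd_simulate(10, 0, cfg0, seed = 4)
  T4 <- cbind(d0$designs[[1]][, 1:2], 1, d0$designs[[1]][, 3])
  expect_equal(d0$responses[[1]], cd_true_f0(T4, cfg0), tolerance = 1e-12)
  ## correlation and scale of the noise generator
  n <- 1e5
  dn <- cd_simulate(n, 0.4, cd_config(), seed = 5)
  T4 <- cbind(dn$designs[[1]][, 1:2], 1, dn$designs[[1]][, 3])
  e0 <- dn$responses[[1]] - cd_true_f0(T4, cd_config())
  T4g <- cbind(dn$designs[[2]][, 1:2], 1, dn$designs[[2]][, 3])
  e1 <- dn$responses[[2]] - cd_gradient(T4g, 1, cd_config())
  expect_lt(abs(cor(e0, e1) - 0.4), 0.01)
  expect_lt(abs(sd(e0) - 0.35) / 0.35, 0.01)
  expect_lt(abs(sd(e1) - 0.35) / 0.35, 0.01)
  ## shared-design option reuses the channel-0 design
  ds <- cd_simulate(10, 0, cd_config(), seed = 6, shared_design = TRUE)
  expect_identical(ds$designs[[1]], ds$designs[[2]])
})

test_that("ion-channel model: identity limit, rate matrix, Frechet derivative", {
  expect_lt(abs(ion_eta(-30, c(0.5, 0.5, 0.5))), 1e-9)
  A1 <- gradspline:::.ion_A(c(1, 1, 1))
  expect_equal(A1[1, ], c(-2, 1, 0, 0))
  expect_equal(A1[4, ], c(0, 0, 1, -1))
  set.seed(7); h <- 1e-6
  for (rep in 1:10) {
    x <- runif(1, -1, 1); tpar <- runif(3, 0.2, 1)
    j <- sample(3, 1)
    e <- h * (1:3 == j)
    fd <- (ion_eta(x, tpar + e) - ion_eta(x, tpar - e)) / (2 * h)
    expect_equal(ion_eta_grad(x, tpar, j), fd, tolerance = 1e-6)
  }
})

test_that("ion simulator: defaults, perfect-fit zero, chain-rule identity", {
  cfg <- ion_config()
  expect_equal(cfg$N, 19L)
  dat <- ion_simulate(4, cfg, seed = 8)
  expect_equal(nrow(attr(dat, "experiment")), 19)
  ## gradient responses equal the analytic derivative of the empirical loss
  f0 <- attr(dat, "truth")
  tp <- dat$designs[[2]][1, , drop = FALSE]
  h <- 1e-6
  fd <- (f0(tp + h * matrix(c(1, 0, 0), 1)) -
         f0(tp - h * matrix(c(1, 0, 0), 1))) / (2 * h)
  expect_equal(dat$responses[[2]][1], fd, tolerance = 1e-6)
  ## with zero measurement noise the loss vanishes at the generating parameter
  cfg0 <- ion_config(noise_sd = 0)
  d0 <- ion_simulate(2, cfg0, seed = 9)
  expect_equal(attr(d0, "truth")(matrix(cfg0$tstar, 1)), 0, tolerance = 1e-20)
  for (j in 1:3)
    expect_equal(attr(d0, "truth_grad")(matrix(cfg0$tstar, 1), j), 0,
                 tolerance = 1e-12)
})

test_that("synthetic truths evaluate and differentiate consistently", {
  tr <- truth_2d()
  set.seed(10); T <- matrix(runif(20), 10, 2)
  h <- 1e-6
  for (j in 1:2) {
    fd <- (truth_eval(tr, fd_shift(T, j, h)) -
           truth_eval(tr, fd_shift(T, j, -h))) / (2 * h)
    expect_equal(truth_grad(tr, T, j), fd, tolerance = 1e-5)
  }
  expect_error(ss_truth(list(list(coef = 1,
    atoms = list(list(j = 1, fun = "tan"))))), "unknown atom")
})

test_that("structured error model: exactness, serial decay, bias, PSD", {
  tr <- truth_additive(2)
  d0 <- ssanova_synthetic(tr, 15, 2, 2, error_model(sigma = 0), seed = 11)
  expect_equal(d0$responses[[1]], truth_eval(tr, d0$designs[[1]]),
               tolerance = 1e-12)
  ## serial autocorrelation tracks (1+h)^(-Upsilon)
  set.seed(12)
  x <- gradspline:::.serial_noise(1e5, 1.5)
  expect_lt(abs(var(x) - 1), 0.03)
  for (h in 1:10) {
    emp <- cor(x[-(1:h)], x[seq_len(1e5 - h)])
    expect_lt(abs(emp - (1 + h)^(-1.5)), 0.02)
  }
  ## bias beta * n^(-3/4)
  set.seed(13)
  E <- gradspline:::.gen_noise(error_model(sigma = 0.01, beta = 1), 1e4, 0)
  expect_lt(abs(mean(E) - 1e-3), 3 * 0.01 / sqrt(1e4))
  ## cross-channel correlation propagates through the mixing
  set.seed(14)
  E2 <- gradspline:::.gen_noise(error_model(sigma = 0.5, rho = 0.6,
                                            Upsilon = 2), 2e4, 1)
  expect_lt(abs(cor(E2[, 1], E2[, 2]) - 0.6), 0.03)
  ## grid design option returns a full lattice
  dg <- ssanova_synthetic(tr, 25, 2, 0, design = "grid", seed = 15)
  expect_equal(dg$n[1], 25L)
  expect_error(error_model(Upsilon = 0.5), "Upsilon")
})
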