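## Data generators for the three applications (option pricing with IPA
## gradients, Cobb-Douglas cost estimation, ion-channel computer model) and a
## generic SS-ANOVA synthetic generator with biased / cross-correlated /
## serially correlated errors.  Every generator returns a `gradient_data`
## object carrying a truth handle (attribute "truth" / "truth_grad") so test
## MSE against the true surface can be estimated by Monte Carlo.

## ---- Black-Scholes option pricing --------------------------------------

#' Configuration for the option-pricing simulator
#'
#' European call under Black-Scholes dynamics with maturity `T = 1` and
#' strike `P0 = 100`; the design variables are the initial price `S0`, the
#' risk-free rate `r`, and the volatility `sigma`, on
#' `[80,120] x [0.01,0.05] x [0.2,1]`.
#'
#' @param k grid points per axis (equally spaced, endpoints included).
#' @param q simulation replications averaged per design point.
#' @return a list of class `bs_config`.
#' @export
bs_config <- function(k = 7L, q = 1000L) {
  stopifnot(k >= 2, q >= 1)
  structure(list(k = as.integer(k), q = as.integer(q), maturity = 1, strike = 100,
                 box = rbind(c(80, 0.01, 0.2), c(120, 0.05, 1))),
            class = "bs_config")
}

#' Closed-form expected option value
#'
#' `f0(S0, r, sigma) = S0 Phi(-d1 + sigma) - 100 e^{-r} Phi(-d1)` with
#' `d1 = [log 100 - log S0 - (r - sigma^2/2)] / sigma`, for maturity 1 and
#' strike 100.  Vectorized.
#'
#' @param S0,r,sigma design coordinates (recycled to a common length).
#' @return expected discounted payoff(s).
#' @export
bs_true_f0 <- function(S0, r, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  d1 <- (log(100) - log(S0) - (r - sigma^2 / 2)) / sigma
  S0 * stats::pnorm(-d1 + sigma) - 100 * exp(-r) * stats::pnorm(-d1)
}

#' Simulate option-pricing data with IPA gradients
#'
#' At each point of the equally spaced design grid, draws `q` i.i.d. standard
#' normals, computes terminal prices
#' `S_T = S0 exp{(r - sigma^2/2) + sigma w}`, and averages the discounted
#' payoff (channel 0) and the three pathwise (infinitesimal perturbation
#' analysis) gradient estimators with respect to `S0`, `r` and `sigma`
#' (channels 1-3) over the same draws.  Draws are independent across design
#' points.  The returned dataset records the per-channel variance of the
#' averaged responses (mean sample variance over the grid divided by `q`) in
#' `sigma2`, so weights and the kriging nugget are available.
#'
#' @param cfg a [bs_config()].
#' @param seed integer seed.
#' @param p number of gradient channels to keep (0-3).
#' @return a [gradient_data()] with attribute `"truth"` (the closed form).
#' @export
bs_simulate <- function(cfg = bs_config(), seed = 1L, p = 3L) {
  stopifnot(inherits(cfg, "bs_config"), p >= 0, p <= 3)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  g <- lapply(1:3, function(j) seq(cfg$box[1, j], cfg$box[2, j], length.out = cfg$k))
  T0 <- as.matrix(expand.grid(S0 = g[[1]], r = g[[2]], sigma = g[[3]],
                              KEEP.OUT.ATTRS = FALSE))
  dimnames(T0) <- NULL
  n <- nrow(T0); q <- cfg$q
  S0 <- T0[, 1]; r <- T0[, 2]; sg <- T0[, 3]
  W <- matrix(stats::rnorm(n * q), n, q)
  ST <- S0 * exp((r - sg^2 / 2) + sg * W)
  disc <- exp(-r)
  itm <- ST >= cfg$strike
  Y0k <- disc * (ST - cfg$strike) * itm
  Y1k <- disc * (ST / S0) * itm
  Y2k <- -Y0k + disc * ST * itm
  Y3k <- disc * (1 / sg) * (log(ST / S0) - (r + sg^2 / 2)) * ST * itm
  chans <- list(Y0k, Y1k, Y2k, Y3k)[seq_len(p + 1L)]
  resp <- lapply(chans, rowMeans)
  pointvar <- lapply(chans, function(M)
    (rowMeans(M^2) - rowMeans(M)^2) * q / ((q - 1) * q))
  s2 <- vapply(pointvar, mean, numeric(1))
  dat <- gradient_data(designs = rep(list(T0), p + 1L), responses = resp,
                       sigma2 = s2, domain = cfg$box)
  attr(dat, "truth") <- function(T) bs_true_f0(T[, 1], T[, 2], T[, 3])
  attr(dat, "q") <- q
  attr(dat, "pointvar") <- pointvar   # per-design-point noise variance of the
                                      # averaged responses, one vector per channel
  dat
}

## ---- Cobb-Douglas cost function ----------------------------------------

#' Configuration for the Cobb-Douglas cost simulator
#'
#' Cost function implied by a Cobb-Douglas production function with
#' efficiency `c0` and elasticities `c1, c2, c3`; observation noise is
#' Gaussian with standard deviation `sd` and cross-channel correlation `rho`
#' at matched indices, on the design box `[0.5, 1.5]^3`.
#'
#' @param c0,c1,c2,c3 positive parameters.
#' @param sd noise standard deviation.
#' @return a list of class `cd_config`.
#' @export
cd_config <- function(c0 = 1, c1 = 0.8, c2 = 0.7, c3 = 0.6, sd = 0.35) {
  stopifnot(c0 > 0, c1 > 0, c2 > 0, c3 > 0, sd >= 0)
  structure(list(c0 = c0, cj = c(c1, c2, c3), csum = c1 + c2 + c3, sd = sd,
                 box = rbind(rep(0.5, 3), rep(1.5, 3))),
            class = "cd_config")
}

#' Cobb-Douglas cost function and its gradient
#'
#' `f0(t1,...,t4) = c0^{-1/c} prod_j (c/c_j)^{c_j/c} prod_j t_j^{c_j/c}
#' t_4^{1/c}` with `c = c1 + c2 + c3`; the first three coordinates are factor
#' prices, the fourth the output level.  `cd_gradient` returns the analytic
#' partial derivative with respect to coordinate `j` (1-4).
#'
#' @param t length-4 vector or `n x 4` matrix of positive inputs.
#' @param cfg a [cd_config()].
#' @return function value(s).
#' @export
cd_true_f0 <- function(t, cfg = cd_config()) {
  T <- if (is.null(dim(t))) matrix(t, nrow = 1) else as.matrix(t)
  if (ncol(T) != 4L) stop("t must have 4 coordinates")
  if (any(T <= 0)) stop("Cobb-Douglas inputs must be positive")
  cs <- cfg$csum
  const <- cfg$c0^(-1 / cs) * prod((cs / cfg$cj)^(cfg$cj / cs))
  v <- const * T[, 1]^(cfg$cj[1] / cs) * T[, 2]^(cfg$cj[2] / cs) *
       T[, 3]^(cfg$cj[3] / cs) * T[, 4]^(1 / cs)
  if (is.null(dim(t))) drop(v) else v
}

#' @rdname cd_true_f0
#' @param j coordinate index 1-4.
#' @export
cd_gradient <- function(t, j, cfg = cd_config()) {
  T <- if (is.null(dim(t))) matrix(t, nrow = 1) else as.matrix(t)
  j <- as.integer(j)
  if (j < 1L || j > 4L) stop("j must be in 1..4")
  expo <- if (j == 4L) 1 / cfg$csum else cfg$cj[j] / cfg$csum
  v <- cd_true_f0(T, cfg) * expo / T[, j]
  if (is.null(dim(t))) drop(v) else v
}

#' Simulate Cobb-Douglas cost data with gradient channels
#'
#' The third price is fixed at 1 (the cost function is homogeneous of degree
#' one in prices), so the effective design is `(t1, t2, t4)` uniform on
#' `[0.5, 1.5]^3`.  Channel 0 observes the cost, channels 1 and 2 its partial
#' derivatives in the first two prices.  Errors are Gaussian with standard
#' deviation `cfg$sd` and pairwise correlation `rho` across the three
#' channels at matched indices.  By default each channel has its own
#' independent design; `shared_design = TRUE` reuses the channel-0 design.
#'
#' @param n sample size per channel.
#' @param rho cross-channel error correlation in `[0, 1)`.
#' @param cfg a [cd_config()].
#' @param seed integer seed.
#' @param shared_design logical.
#' @param p number of gradient channels (0, 1 or 2).
#' @return a [gradient_data()] with truth handles attached.
#' @export
cd_simulate <- function(n, rho = 0, cfg = cd_config(), seed = 1L,
                        shared_design = FALSE, p = 2L) {
  stopifnot(n >= 1, rho >= 0, rho < 1, p >= 0, p <= 2)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  full <- function(T3) cbind(T3[, 1], T3[, 2], 1, T3[, 3])
  designs <- vector("list", p + 1L)
  for (jc in 0:p) {
    designs[[jc + 1L]] <- if (shared_design && jc > 0L) designs[[1L]]
      else matrix(stats::runif(3 * n, 0.5, 1.5), n, 3)
  }
  ## equicorrelated Gaussian errors across channels at matched index
  R <- matrix(rho, 3, 3); diag(R) <- 1
  E <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(R) * cfg$sd
  resp <- vector("list", p + 1L)
  for (jc in 0:p) {
    T4 <- full(designs[[jc + 1L]])
    mu <- if (jc == 0L) cd_true_f0(T4, cfg) else cd_gradient(T4, jc, cfg)
    resp[[jc + 1L]] <- mu + E[, jc + 1L]
  }
  dat <- gradient_data(designs, resp, sigma2 = rep(cfg$sd^2, p + 1L),
                       domain = cfg$box)
  attr(dat, "truth") <- function(T) cd_true_f0(cbind(T[, 1], T[, 2], 1, T[, 3]), cfg)
  attr(dat, "truth_grad") <- function(T, j)
    cd_gradient(cbind(T[, 1], T[, 2], 1, T[, 3]), j, cfg)
  dat
}

## ---- ion-channel computer model ----------------------------------------

#' Configuration for the ion-channel simulator
#'
#' Synthetic version of a voltage-clamp experiment on a sodium channel: the
#' computer model is `eta(x, t) = e1' expm(e^x A(t)) e4` with a 4 x 4 rate
#' matrix `A(t)` in the calibration parameter `t` and `x` the log time.  The
#' synthetic experiment generates `N` (log-time, normalized current) pairs
#' from a generating parameter `tstar` plus measurement noise.
#'
#' @param tstar generating parameter in `(0, 1]^3`.
#' @param N number of experiment pairs.
#' @param noise_sd measurement noise standard deviation.
#' @param x_range range of the equally spaced log-time grid.
#' @return a list of class `ion_config`.
#' @export
ion_config <- function(tstar = c(0.5, 0.5, 0.5), N = 19L, noise_sd = 0.02,
                       x_range = c(0, 1)) {
  stopifnot(length(tstar) == 3, all(tstar > 0), all(tstar <= 1), N >= 2)
  structure(list(tstar = as.numeric(tstar), N = as.integer(N),
                 noise_sd = noise_sd, x_range = x_range),
            class = "ion_config")
}

.ion_A <- function(t) {
  t1 <- t[1]; t2 <- t[2]; t3 <- t[3]
  matrix(c(-t2 - t3, t1,            0,         0,
           t2,       -t1 - t2,      t1,        0,
           0,         t2,           -t1 - t2,  t1,
           0,         0,            t2,        -t1),
         4, 4, byrow = TRUE)
}

.ion_dA <- function(j) {
  switch(j,
    matrix(c(0, 1, 0, 0,  0, -1, 1, 0,  0, 0, -1, 1,  0, 0, 0, -1), 4, 4, byrow = TRUE),
    matrix(c(-1, 0, 0, 0,  1, -1, 0, 0,  0, 1, -1, 0,  0, 0, 1, 0), 4, 4, byrow = TRUE),
    matrix(c(-1, 0, 0, 0,  0, 0, 0, 0,   0, 0, 0, 0,   0, 0, 0, 0), 4, 4, byrow = TRUE))
}

#' Ion-channel computer model and its parameter gradient
#'
#' `ion_eta` evaluates `e1' expm(e^x A(t)) e4`; `ion_eta_grad` returns the
#' exact partial derivative in `t_j` via the Frechet derivative of the matrix
#' exponential, computed from the 8 x 8 block-augmented exponential
#' `expm([[M, E], [0, M]])` whose top-right block is the directional
#' derivative.
#'
#' @param x log-time input (vectorized).
#' @param t calibration parameter, length 3, components in `(0, 1]`.
#' @return model value(s).
#' @export
ion_eta <- function(x, t) {
  A <- .ion_A(t)
  vapply(x, function(xi) {
    M <- as.matrix(Matrix::expm(exp(xi) * A))
    M[1, 4]
  }, numeric(1))
}

#' @rdname ion_eta
#' @param j parameter coordinate 1-3.
#' @export
ion_eta_grad <- function(x, t, j) {
  A <- .ion_A(t); dA <- .ion_dA(as.integer(j))
  vapply(x, function(xi) {
    M <- exp(xi) * A; E <- exp(xi) * dA
    Big <- rbind(cbind(M, E), cbind(matrix(0, 4, 4), M))
    as.matrix(Matrix::expm(Big))[1, 8]
  }, numeric(1))
}

#' Simulate ion-channel calibration data
#'
#' Generates a synthetic experiment: `N` log-times equally spaced on
#' `cfg$x_range` with normalized currents `z_k = eta(x_k, tstar) + noise`
#' (or uses supplied real data verbatim).  The estimation target is the
#' empirical discrepancy `f0(t) = (1/N) sum_k [z_k - eta(x_k, t)]^2`;
#' channel 0 observes `f0` at its design points and channel `j` observes the
#' exact analytic gradient `-2/N sum_k [z_k - eta(x_k, t)] d eta / d t_j`.
#'
#' @param n design points per channel (i.i.d. uniform in `(0, 1]^3`).
#' @param cfg an [ion_config()].
#' @param seed integer seed.
#' @param p number of gradient channels (0-3).
#' @param real_data optional two-column matrix / data frame (x, z) replacing
#'   the synthetic experiment pairs.
#' @return a [gradient_data()] with the experiment pairs in attribute
#'   `"experiment"` and a truth handle.
#' @export
ion_simulate <- function(n, cfg = ion_config(), seed = 1L, p = 3L,
                         real_data = NULL) {
  stopifnot(n >= 1, p >= 0, p <= 3)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  if (is.null(real_data)) {
    xk <- seq(cfg$x_range[1], cfg$x_range[2], length.out = cfg$N)
    zk <- ion_eta(xk, cfg$tstar) + stats::rnorm(cfg$N, 0, cfg$noise_sd)
  } else {
    rd <- as.matrix(real_data)
    if (ncol(rd) != 2L || nrow(rd) < 2L || any(!is.finite(rd)))
      stop("real_data must be a numeric two-column (x, z) table")
    xk <- rd[, 1]; zk <- rd[, 2]
  }
  N <- length(xk)
  f0 <- function(T) {
    T <- as.matrix(T)
    vapply(seq_len(nrow(T)), function(i)
      mean((zk - ion_eta(xk, T[i, ]))^2), numeric(1))
  }
  g0 <- function(T, j) {
    T <- as.matrix(T)
    vapply(seq_len(nrow(T)), function(i) {
      res <- zk - ion_eta(xk, T[i, ])
      -2 * mean(res * ion_eta_grad(xk, T[i, ], j))
    }, numeric(1))
  }
  eps <- 1e-6   # keep designs strictly positive
  designs <- lapply(0:p, function(jc) matrix(stats::runif(3 * n, eps, 1), n, 3))
  resp <- lapply(0:p, function(jc) {
    if (jc == 0L) f0(designs[[jc + 1L]]) else g0(designs[[jc + 1L]], jc)
  })
  dat <- gradient_data(designs, resp, domain = .default_domain(3))
  attr(dat, "truth") <- f0
  attr(dat, "truth_grad") <- g0
  attr(dat, "experiment") <- cbind(x = xk, z = zk)
  dat
}

## ---- generic SS-ANOVA synthetic generator ------------------------------

#' Error model for synthetic SS-ANOVA data
#'
#' Noise structure allowing bias, cross-channel correlation, and short-range
#' serial correlation: mean `beta * n^{-3/4}` (an `o(n^{-1/2})` bias),
#' autocovariance envelope `sigma^2 (1 + h)^{-Upsilon}` in the observation
#' index, and pairwise correlation `rho` across channels at matched indices.
#' `Upsilon = Inf` gives serially independent errors.
#'
#' @param sigma per-channel noise standard deviation(s).
#' @param rho cross-channel correlation in `[0, 1)`.
#' @param Upsilon serial correlation decay exponent, `> 1`.
#' @param beta bias scale `>= 0`.
#' @return a list of class `error_model`.
#' @export
error_model <- function(sigma = 0.3, rho = 0, Upsilon = Inf, beta = 0) {
  stopifnot(all(sigma >= 0), rho >= 0, rho < 1, Upsilon > 1, beta >= 0)
  structure(list(sigma = sigma, rho = rho, Upsilon = Upsilon, beta = beta),
            class = "error_model")
}

## Stationary unit-variance Gaussian series with autocovariance
## (1 + h)^{-Upsilon}, via circulant embedding (negative spectral mass, if
## any, clipped to zero -- a nearest-PSD projection of the embedding).
.serial_noise <- function(n, Upsilon) {
  if (!is.finite(Upsilon)) return(stats::rnorm(n))
  if (n == 1L) return(stats::rnorm(1))
  g <- (1 + 0:(n - 1))^(-Upsilon)
  g[1] <- 1
  m <- 2L * (n - 1L)
  crow <- c(g, g[(n - 1):2])
  lam <- pmax(Re(stats::fft(crow)), 0)
  ## unit-variance complex normals: Re of the synthesis then has covariance
  ## equal to the circulant row exactly
  xi <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  Re(stats::fft(sqrt(lam) * xi))[seq_len(n)] / sqrt(m)
}

## n x (p+1) noise matrix under an error_model
.gen_noise <- function(em, n, p) {
  k <- p + 1L
  sig <- rep_len(em$sigma, k)
  E <- vapply(seq_len(k), function(j) .serial_noise(n, em$Upsilon),
              numeric(n))
  E <- matrix(E, n, k)
  R <- matrix(em$rho, k, k); diag(R) <- 1
  E <- E %*% chol(R)
  E <- sweep(E, 2, sig, "*")
  E + em$beta * n^(-3 / 4)
}

#' Smooth truth specification for the synthetic generator
#'
#' A truth is a sum of terms; each term is a coefficient times a product of
#' univariate atoms acting on distinct coordinates.  Atoms: `"sin"` and
#' `"cos"` (argument `2 * pi * par * t`), `"poly"` (`t^par`), `"lin"` (`t`).
#'
#' @param terms list of terms; each term is
#'   `list(coef = , atoms = list(list(j = , fun = , par = ), ...))`.
#' @return an object of class `ss_truth` with analytic gradient support.
#' @examples
#' tr <- ss_truth(list(
#'   list(coef = 1, atoms = list(list(j = 1, fun = "sin", par = 1))),
#'   list(coef = 1, atoms = list(list(j = 2, fun = "cos", par = 1)))))
#' @export
ss_truth <- function(terms) {
  for (tm in terms) {
    stopifnot(is.numeric(tm$coef), length(tm$atoms) >= 1)
    js <- vapply(tm$atoms, function(a) as.integer(a$j), integer(1))
    if (anyDuplicated(js)) stop("atoms of one term must act on distinct coordinates")
    for (a in tm$atoms)
      if (!a$fun %in% c("sin", "cos", "poly", "lin"))
        stop("unknown atom '", a$fun, "'")
  }
  structure(list(terms = terms), class = "ss_truth")
}

.atom_eval <- function(a, t, deriv = FALSE) {
  par <- a$par %||% 1
  switch(a$fun,
    sin  = if (deriv) 2 * pi * par * cos(2 * pi * par * t) else sin(2 * pi * par * t),
    cos  = if (deriv) -2 * pi * par * sin(2 * pi * par * t) else cos(2 * pi * par * t),
    poly = if (deriv) par * t^(par - 1) else t^par,
    lin  = if (deriv) rep(1, length(t)) else t)
}

#' Evaluate a synthetic truth or its gradient
#'
#' @param truth an [ss_truth()].
#' @param T `n x d` matrix of points.
#' @param j gradient coordinate for `truth_grad`.
#' @return numeric vector.
#' @export
truth_eval <- function(truth, T) {
  T <- as.matrix(T)
  out <- numeric(nrow(T))
  for (tm in truth$terms) {
    v <- rep(tm$coef, nrow(T))
    for (a in tm$atoms) v <- v * .atom_eval(a, T[, a$j])
    out <- out + v
  }
  out
}

#' @rdname truth_eval
#' @export
truth_grad <- function(truth, T, j) {
  T <- as.matrix(T)
  out <- numeric(nrow(T))
  for (tm in truth$terms) {
    js <- vapply(tm$atoms, function(a) as.integer(a$j), integer(1))
    if (!j %in% js) next
    v <- rep(tm$coef, nrow(T))
    for (a in tm$atoms) v <- v * .atom_eval(a, T[, a$j], deriv = (a$j == j))
    out <- out + v
  }
  out
}

#' Generic synthetic SS-ANOVA data with structured errors
#'
#' Generates designs (i.i.d. uniform or an equally spaced lattice) on the
#' unit cube, evaluates a smooth truth and its analytic partial derivatives,
#' and adds noise from an [error_model()] (bias, serial correlation along the
#' observation index, cross-channel correlation at matched indices).
#'
#' @param truth an [ss_truth()].
#' @param n sample size per channel (for `design = "grid"` it is rounded to
#'   the nearest full lattice `m^d`).
#' @param d dimension.
#' @param p number of gradient channels.
#' @param errors an [error_model()].
#' @param design `"random"` or `"grid"`.
#' @param seed integer seed.
#' @return a [gradient_data()] with truth handles attached.
#' @export
ssanova_synthetic <- function(truth, n, d, p, errors = error_model(),
                              design = c("random", "grid"), seed = 1L) {
  stopifnot(inherits(truth, "ss_truth"), p >= 0, p <= d)
  design <- match.arg(design)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  make_design <- function() {
    if (design == "random") matrix(stats::runif(n * d), n, d)
    else {
      m <- max(2L, round(n^(1 / d)))
      as.matrix(expand.grid(rep(list(seq(0, 1, length.out = m)), d),
                            KEEP.OUT.ATTRS = FALSE))
    }
  }
  designs <- lapply(0:p, function(jc) {
    D <- make_design(); dimnames(D) <- NULL; D
  })
  nr <- nrow(designs[[1]])
  E <- .gen_noise(errors, nr, p)
  resp <- lapply(0:p, function(jc) {
    mu <- if (jc == 0L) truth_eval(truth, designs[[jc + 1L]])
          else truth_grad(truth, designs[[jc + 1L]], jc)
    mu + E[, jc + 1L]
  })
  dat <- gradient_data(designs, resp, domain = .default_domain(d))
  attr(dat, "truth") <- function(T) truth_eval(truth, T)
  attr(dat, "truth_grad") <- function(T, j) truth_grad(truth, T, j)
  dat
}
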