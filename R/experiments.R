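## Scripted experiments reproducing the simulation studies at configurable
## replication counts, plus dataset file I/O and the empirical-rate study.

#' Read or write a gradient dataset as delimited text
#'
#' File schema (header row, comma separated): `channel` (integer `0..p`),
#' `t1..td` (doubles), `y` (double).  The reader validates the schema and the
#' dataset invariants and names the offending row in error messages.
#'
#' @param path file path.
#' @param domain optional `2 x d` box (default unit cube).
#' @param sigma2 optional known channel variances.
#' @return `read_gradient_data`: a [gradient_data()].
#' @export
read_gradient_data <- function(path, domain = NULL, sigma2 = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("channel", "y")
  if (!all(need %in% names(df)))
    stop("missing required column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  tcols <- grep("^t[0-9]+$", names(df), value = TRUE)
  if (length(tcols) == 0L) stop("no design columns t1..td found")
  tcols <- paste0("t", seq_along(tcols))
  if (!all(tcols %in% names(df))) stop("design columns must be consecutive t1..td")
  d <- length(tcols)
  ch <- df$channel
  bad <- which(!is.finite(ch) | ch != floor(ch) | ch < 0 | ch > d)
  if (length(bad))
    stop("row ", bad[1], ": invalid channel index ", ch[bad[1]])
  p <- max(ch)
  if (!0 %in% ch) stop("channel 0 (function data) is mandatory")
  if (!all(0:p %in% ch))
    stop("channels must be contiguous 0..p; missing ",
         paste(setdiff(0:p, unique(ch)), collapse = ", "))
  designs <- lapply(0:p, function(j) {
    M <- as.matrix(df[ch == j, tcols, drop = FALSE])
    dimnames(M) <- NULL
    M
  })
  responses <- lapply(0:p, function(j) df$y[ch == j])
  dat <- tryCatch(
    gradient_data(designs, responses, d = d, sigma2 = sigma2, domain = domain),
    error = function(e) stop("invalid dataset in ", path, ": ", conditionMessage(e)))
  dat
}

#' @rdname read_gradient_data
#' @param data a [gradient_data()].
#' @export
write_gradient_data <- function(data, path) {
  stopifnot(inherits(data, "gradient_data"))
  rows <- lapply(0:data$p, function(j) {
    Tj <- data$designs[[j + 1L]]
    colnames(Tj) <- paste0("t", seq_len(data$d))
    cbind(data.frame(channel = j), as.data.frame(Tj),
          data.frame(y = data$responses[[j + 1L]]))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## MSE of a prediction function against a truth handle over fresh uniform
## test points in the box.
.test_mse <- function(predict_fun, truth_fun, domain, n_test, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  d <- ncol(domain)
  U <- matrix(stats::runif(n_test * d), n_test, d)
  Tt <- sweep(sweep(U, 2, .box_widths(domain), "*"), 2, domain[1, ], "+")
  mean((predict_fun(Tt) - truth_fun(Tt))^2)
}

#' Cobb-Douglas simulation study (mean MSE per setting)
#'
#' For each requested cell `(n, rho, p)` runs `reps` replicates: simulate
#' with [cd_simulate()], fit [gradspline()] with `s = n/10` features per
#' coordinate and weights from the known (equal) channel variances, and
#' estimate the MSE against the closed-form truth over `n_test` fresh
#' uniform test points.  A common kernel scale per cell is selected by
#' five-fold cross-validation with the score pooled over three replicate
#' datasets, and reused across replicates (pooling removes the visible
#' selection noise of a single replicate).
#'
#' @param n,rho,p vectors defining the cells (crossed).
#' @param reps replicates per cell.
#' @param seed master seed; every replicate derives child seeds.
#' @param n_test Monte Carlo test points for the MSE.
#' @param scales fixed kernel scale, or `"cv"` (default) for per-cell
#'   selection.
#' @param verbose print one line per cell.
#' @return data frame with columns `n, rho, p, reps, mean_mse, sd_mse,
#'   se_mean, mean_mse_1e4` (the latter in units of `1e-4`).
#' @export
run_table2 <- function(n = c(100, 200), rho = 0, p = c(0, 2), reps = 200,
                       seed = 1L, n_test = 10000L, scales = "cv",
                       verbose = FALSE) {
  cells <- expand.grid(n = n, rho = rho, p = p, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cells))
  cfg <- cd_config()
  seeds <- .child_seeds(seed, nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    ni <- cells$n[ci]; rhoi <- cells$rho[ci]; pi <- cells$p[ci]
    rs <- .child_seeds(seeds[ci], 3L * reps)
    sc <- scales
    if (identical(scales, "cv")) {
      ## pool the CV score over three replicate datasets: a single replicate's
      ## scale pick is noisy enough to move the cell mean visibly
      d0 <- lapply(1:3, function(k)
        cd_simulate(ni, rhoi, cfg, seed = rs[1] + k - 1L, p = pi))
      sc <- .cv_scales(d0, "matern52", s = max(5L, ceiling(ni / 10)), r = 3,
                       scale_grid = exp(seq(log(0.1), log(2), length.out = 8)), folds = 5L,
                       weights = NULL, seed = rs[2])
    }
    mses <- vapply(seq_len(reps), function(rep) {
      dat <- cd_simulate(ni, rhoi, cfg, seed = rs[3 * rep - 2], p = pi)
      ft <- gradspline(dat, kernel = "matern52", scales = sc, seed = rs[3 * rep - 1])
      .test_mse(function(Tt) predict(ft, Tt), attr(dat, "truth"),
                dat$domain, n_test, rs[3 * rep])
    }, numeric(1))
    out[[ci]] <- data.frame(n = ni, rho = rhoi, p = pi, reps = reps,
                            scale = sc,
                            mean_mse = mean(mses), sd_mse = stats::sd(mses),
                            se_mean = stats::sd(mses) / sqrt(reps),
                            mean_mse_1e4 = mean(mses) * 1e4)
    if (verbose)
      message(sprintf("n=%d rho=%.1f p=%d: mean MSE = %.4f e-4 (sd %.4f e-4)",
                      ni, rhoi, pi, mean(mses) * 1e4, stats::sd(mses) * 1e4))
  }
  do.call(rbind, out)
}

#' Option-pricing ratio study (gradient estimator vs stochastic kriging)
#'
#' Per replicate: simulate the option-pricing experiment on a `k^3` equally
#' spaced grid with `q` averaged replications per point, fit the
#' gradient-augmented estimator with the first two gradient channels
#' (`p = 2`) and stochastic kriging on function data only, and estimate both
#' MSEs against the closed form over `n_test` uniform test points.  Reports
#' the ratio of mean MSEs.
#'
#' @param k grid points per axis.
#' @param q replications per design point.
#' @param reps replicates.
#' @param seed master seed.
#' @param n_test test points.
#' @param scales kernel scale for the gradient estimator (`"cv"`: five-fold
#'   selection pooled over two replicates).
#' @param verbose print per-replicate lines.
#' @return data frame with mean MSEs of both methods and their ratio.
#' @export
run_table1 <- function(k = 7L, q = 1000L, reps = 100, seed = 1L,
                       n_test = 10000L, scales = "cv", verbose = FALSE) {
  cfg <- bs_config(k = k, q = q)
  rs <- .child_seeds(seed, 4L * reps + 3L)
  sc <- scales
  d0 <- bs_simulate(cfg, seed = rs[4L * reps + 1L], p = 2L)
  if (identical(scales, "cv")) {
    d0b <- bs_simulate(cfg, seed = rs[4L * reps + 1L] + 1L, p = 2L)
    sc <- .cv_scales(list(d0, d0b), "matern52",
                     s = max(5L, ceiling(d0$n[1] / 10)), r = 3,
                     scale_grid = exp(seq(log(0.1), log(2), length.out = 8)), folds = 5L,
                     weights = NULL, seed = rs[4L * reps + 2L])
  }
  ## kriging lengthscale: five-fold CV once on the first replicate, reused
  kr0 <- sk_fit(d0, seed = rs[4L * reps + 3L])
  sck <- kr0$tau
  mse_g <- mse_k <- numeric(reps)
  for (rep in seq_len(reps)) {
    dat <- bs_simulate(cfg, seed = rs[4 * rep - 3], p = 2L)
    ft <- gradspline(dat, kernel = "matern52", scales = sc, seed = rs[4 * rep - 2])
    kr <- sk_fit(dat, scales = sck, seed = rs[4 * rep - 1])
    mse_g[rep] <- .test_mse(function(Tt) predict(ft, Tt), attr(dat, "truth"),
                            dat$domain, n_test, rs[4 * rep])
    mse_k[rep] <- .test_mse(function(Tt) predict(kr, Tt), attr(dat, "truth"),
                            dat$domain, n_test, rs[4 * rep])
    if (verbose)
      message(sprintf("rep %d: gradient %.4g, kriging %.4g", rep,
                      mse_g[rep], mse_k[rep]))
  }
  data.frame(n = cfg$k^3, q = q, reps = reps, scale = sc,
             mean_mse_gradient = mean(mse_g), mean_mse_kriging = mean(mse_k),
             ratio = mean(mse_g) / mean(mse_k),
             se_ratio = stats::sd(mse_g / mean(mse_k)) / sqrt(reps))
}

#' Log-log slope of mean MSE against sample size
#'
#' Least-squares slope (with standard error) of `log(mean MSE)` on `log(n)`.
#'
#' @param n sample sizes.
#' @param mse mean MSE at each `n`.
#' @return list with `slope` and `se`.
#' @export
rate_slope <- function(n, mse) {
  stopifnot(length(n) == length(mse), length(n) >= 2, all(mse > 0))
  fit <- stats::lm(log(mse) ~ log(n))
  ## suppressWarnings: summary.lm warns on an exactly collinear (perfect) fit
  list(slope = unname(stats::coef(fit)[2]),
       se = suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2])))
}

#' Empirical convergence-rate study
#'
#' Fits the estimator over a ladder of sample sizes for an additive truth and
#' regresses log mean MSE on log n, for each requested number of gradient
#' channels.  With full gradient data on an additive model the slope is
#' expected near -1 (parametric rate); with function data only it is
#' expected shallower.
#'
#' @param n_ladder sample sizes.
#' @param reps replicates per sample size.
#' @param d dimension.
#' @param p_set numbers of gradient channels to compare.
#' @param truth an [ss_truth()] (default: additive sin/cos in each
#'   coordinate).
#' @param errors an [error_model()] (default sd 0.3, independent).
#' @param seed master seed.
#' @param n_test test points per MSE estimate.
#' @param scales kernel scale in unit-cube coordinates, or `"cv"` (default)
#'   for five-fold selection pooled over three replicates of each `(p, n)`
#'   cell, matching the protocol of the table experiments.
#' @return list with a per-(p, n) table and per-p slopes.
#' @export
run_rates <- function(n_ladder = c(100, 200, 400, 800), reps = 200, d = 2L,
                      p_set = c(0L, d), truth = NULL,
                      errors = error_model(sigma = 0.3), seed = 1L,
                      n_test = 2000L, scales = "cv") {
  truth <- truth %||% ss_truth(lapply(seq_len(d), function(j)
    list(coef = 1, atoms = list(list(j = j, fun = if (j %% 2) "sin" else "cos",
                                     par = 1)))))
  grid <- expand.grid(n = n_ladder, p = p_set, KEEP.OUT.ATTRS = FALSE)
  seeds <- .child_seeds(seed, nrow(grid))
  tab <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    ni <- grid$n[gi]; pi <- grid$p[gi]
    rs <- .child_seeds(seeds[gi], 3L * reps + 2L)
    sc <- scales
    if (identical(scales, "cv")) {
      d0 <- lapply(1:3, function(k)
        ssanova_synthetic(truth, ni, d, pi, errors,
                          seed = rs[3L * reps + 1L] + k - 1L))
      sc <- .cv_scales(d0, "matern52", s = max(5L, ceiling(ni / 10)), r = 1,
                       scale_grid = exp(seq(log(0.1), log(2), length.out = 8)),
                       folds = 5L, weights = NULL, seed = rs[3L * reps + 2L])
    }
    mses <- vapply(seq_len(reps), function(rep) {
      dat <- ssanova_synthetic(truth, ni, d, pi, errors, seed = rs[3 * rep - 2])
      ft <- gradspline(dat, scales = sc, r = 1L, seed = rs[3 * rep - 1])
      .test_mse(function(Tt) predict(ft, Tt), attr(dat, "truth"),
                dat$domain, n_test, rs[3 * rep])
    }, numeric(1))
    tab[[gi]] <- data.frame(p = pi, n = ni, reps = reps, mean_mse = mean(mses),
                            se = stats::sd(mses) / sqrt(reps))
  }
  tab <- do.call(rbind, tab)
  slopes <- lapply(p_set, function(pi) {
    sub <- tab[tab$p == pi, ]
    c(p = pi, unlist(rate_slope(sub$n, sub$mean_mse)))
  })
  list(table = tab, slopes = do.call(rbind, slopes))
}
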