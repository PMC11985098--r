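#' Gradient regression dataset
#'
#' Container for function-value and partial-derivative observations.  Channel
#' 0 holds noisy function values `y = f(t) + e`; channel `j` in `1..p` holds
#' noisy partial derivatives `y = df/dt_j (t) + e`.  Channels may have
#' different sample sizes; channel 0 is mandatory because it anchors the
#' absolute level of the function.
#'
#' @param designs list of `p + 1` design matrices (`n_j x d`), channels
#'   `0..p` in order.
#' @param responses list of `p + 1` numeric response vectors.
#' @param d dimension; defaults to `ncol(designs[[1]])`.
#' @param sigma2 optional numeric vector of known per-channel noise variances
#'   (length `p + 1`).
#' @param domain `2 x d` matrix of box bounds (row 1 lower, row 2 upper);
#'   defaults to the unit cube.
#' @return an object of class `gradient_data`.
#' @export
gradient_data <- function(designs, responses, d = NULL, sigma2 = NULL,
                          domain = NULL) {
  if (!is.list(designs) || !is.list(responses) ||
      length(designs) != length(responses) || length(designs) < 1L)
    stop("designs and responses must be lists of equal length >= 1")
  designs <- lapply(designs, as.matrix)
  d <- as.integer(d %||% ncol(designs[[1]]))
  p <- length(designs) - 1L
  if (p > d) stop("number of gradient channels p must be <= d")
  domain <- domain %||% .default_domain(d)
  domain <- matrix(as.numeric(domain), 2, d)
  if (any(domain[2, ] <= domain[1, ])) stop("domain upper bounds must exceed lower")
  for (j in seq_along(designs)) {
    Tj <- designs[[j]]
    if (ncol(Tj) != d) stop("channel ", j - 1L, ": design has wrong dimension")
    if (nrow(Tj) < 1L) stop("channel ", j - 1L, ": empty design")
    if (length(responses[[j]]) != nrow(Tj))
      stop("channel ", j - 1L, ": response length does not match design")
    if (any(!is.finite(Tj)) || any(!is.finite(responses[[j]])))
      stop("channel ", j - 1L, ": non-finite values")
    eps <- 1e-8 * .box_widths(domain)
    ok <- sweep(Tj, 2, domain[1, ] - eps, ">=") & sweep(Tj, 2, domain[2, ] + eps, "<=")
    if (!all(ok)) stop("channel ", j - 1L, ": design points outside the domain box")
  }
  if (!is.null(sigma2)) {
    sigma2 <- as.numeric(sigma2)
    if (length(sigma2) != p + 1L || any(sigma2 < 0))
      stop("sigma2 must be a nonnegative vector of length p + 1")
  }
  structure(list(d = d, p = p, designs = designs,
                 responses = lapply(responses, as.numeric),
                 sigma2 = sigma2, domain = domain,
                 n = vapply(designs, nrow, integer(1))),
            class = "gradient_data")
}

#' @export
print.gradient_data <- function(x, ...) {
  cat(sprintf("gradient_data: d = %d, p = %d gradient channel(s)\n", x$d, x$p))
  cat("  n per channel:", paste(x$n, collapse = ", "), "\n")
  invisible(x)
}

#' Per-channel weights from noise variances
#'
#' Weights are `w_j = sigma_0^2 / sigma_j^2`.  If variances are not supplied
#' in the dataset they are estimated per channel by the nearest-neighbour
#' squared-difference estimator: points are ordered by their first principal
#' coordinate and `sigma^2 = sum (y_(i+1) - y_(i))^2 / (2 (n - 1))`.  Channels
#' with fewer than 3 points fall back to weight 1.
#'
#' @param data a [gradient_data()] object.
#' @return numeric vector of `p` weights (empty when `p = 0`).
#' @export
estimate_weights <- function(data) {
  stopifnot(inherits(data, "gradient_data"))
  p <- data$p
  if (p == 0L) return(numeric(0))
  if (!is.null(data$sigma2)) {
    s2 <- data$sigma2
    if (any(s2[-1] == 0)) stop("gradient channel variance of 0 is not usable")
    return(s2[1] / s2[-1])
  }
  est <- vapply(seq_len(p + 1L), function(jc) {
    Tj <- data$designs[[jc]]; y <- data$responses[[jc]]
    n <- length(y)
    if (n < 3L) return(NA_real_)
    pc1 <- if (ncol(Tj) == 1L) Tj[, 1] else stats::prcomp(Tj)$x[, 1]
    ys <- y[order(pc1)]
    sum(diff(ys)^2) / (2 * (n - 1))
  }, numeric(1))
  if (any(is.na(est)) || any(est[-1] <= 0)) return(rep(1, p))
  est[1] / est[-1]
}

#' Assemble the stacked weighted ridge system
#'
#' Stacks channel-0 rows (function kind, weight 1) and channel-`j` rows
#' (gradient kind, weight `w_j`) into one regression system for the
#' derivative-augmented feature model, with an unpenalized intercept column
#' that is 1 on function rows and 0 on gradient rows.  Each channel's squared
#' loss is divided by its own sample size, so the row weight is `w_j / n_j`.
#' Designs are mapped into the unit cube and gradient responses rescaled by
#' the box width (chain rule), so kernel scales always refer to unit-cube
#' coordinates.
#'
#' @param data a [gradient_data()] object.
#' @param basis an [build_basis()] object with matching dimension.
#' @param weights numeric vector of `p` channel weights.
#' @return an object of class `grad_system`.
#' @export
assemble_system <- function(data, basis, weights = NULL) {
  stopifnot(inherits(data, "gradient_data"), inherits(basis, "rf_basis"))
  if (basis$d != data$d) stop("basis dimension does not match data")
  p <- data$p
  weights <- weights %||% if (p > 0L) estimate_weights(data) else numeric(0)
  if (length(weights) != p || any(weights <= 0))
    stop("weights must be ", p, " positive values")
  wid <- .box_widths(data$domain)
  Tl <- list(); yl <- list(); kl <- list(); vl <- list()
  for (jc in 0:p) {
    Tj <- .to_unit(data$designs[[jc + 1L]], data$domain)
    yj <- data$responses[[jc + 1L]]
    if (jc > 0L) yj <- yj * wid[jc]            # df/du = df/dt * width
    nj <- nrow(Tj)
    ## residuals of the rescaled gradient channel are width_j times the
    ## original ones, so the inverse-variance weight picks up width^-2
    w <- if (jc == 0L) 1 else weights[jc] / wid[jc]^2
    Tl[[jc + 1L]] <- Tj; yl[[jc + 1L]] <- yj
    kl[[jc + 1L]] <- rep(jc, nj); vl[[jc + 1L]] <- rep(w / nj, nj)
  }
  T <- do.call(rbind, Tl)
  structure(list(basis = basis, T = T, kinds = unlist(kl),
                 y = unlist(yl), v = unlist(vl),
                 z = as.numeric(unlist(kl) == 0L),
                 N = nrow(T), p = p, weights = weights,
                 D_total = (p + 1L) * basis$D, domain = data$domain),
            class = "grad_system")
}

## ---- solvers -----------------------------------------------------------
## Objective: sum_i v_i (y_i - x_i' c - z_i a)^2 + lambda ||c||^2 with the
## intercept a unpenalized.  Work with rows scaled by sqrt(v); the intercept
## is projected out, the ridge solved on the projected system, and the
## intercept recovered.

.sys_scaled <- function(system) {
  sv <- sqrt(system$v)
  list(sv = sv, yt = sv * system$y, zt = sv * system$z,
       zn2 = sum((sv * system$z)^2))
}

## primal: explicit design matrix
.solve_primal <- function(system, lambda, X = NULL) {
  sc <- .sys_scaled(system)
  X <- X %||% .design_matrix(system$basis, system$T, system$kinds, system$p)
  Xt <- X * sc$sv
  ## project out intercept
  zb <- sc$zt / sqrt(sc$zn2)
  Xp <- Xt - zb %o% drop(crossprod(zb, Xt))
  yp <- sc$yt - zb * sum(zb * sc$yt)
  A <- crossprod(Xp)
  diag(A) <- diag(A) + lambda
  ch <- tryCatch(chol(A), error = function(e)
    stop("singular ridge system (increase lambda)"))
  chsolve <- function(b) backsolve(ch, backsolve(ch, b, transpose = TRUE))
  b <- crossprod(Xp, yp)
  cvec <- chsolve(b)
  cvec <- cvec + chsolve(b - A %*% cvec)     # one refinement step
  a <- sum(sc$zt * (sc$yt - Xt %*% cvec)) / sc$zn2
  fitted_t <- drop(Xt %*% cvec) + sc$zt * a
  list(coef = drop(cvec), intercept = a,
       fitted = fitted_t / sc$sv, X = X)
}

## dual: factorized Gram
.solve_dual <- function(system, lambda, G = NULL) {
  sc <- .sys_scaled(system)
  G <- G %||% factorized_gram(system$basis, system$T, system$kinds, system$p)
  Gt <- G * tcrossprod(sc$sv)                 # sqrt(V) G sqrt(V)
  zb <- sc$zt / sqrt(sc$zn2)
  P <- function(x) x - zb * sum(zb * x)
  Gp <- Gt - zb %o% drop(crossprod(zb, Gt))
  Gp <- Gp - drop(Gp %*% zb) %o% zb
  diag(Gp) <- diag(Gp) + lambda
  yp <- P(sc$yt)
  alpha <- tryCatch({
    ch <- chol(Gp)
    chsolve <- function(b) backsolve(ch, backsolve(ch, b, transpose = TRUE))
    a0 <- chsolve(yp)
    a0 + chsolve(yp - Gp %*% a0)             # one refinement step
  }, error = function(e) tryCatch(solve(Gp, yp), error = function(e2)
    stop("singular ridge system (increase lambda)")))
  gamma <- sc$sv * P(alpha)                   # c = X' gamma
  fitted_core <- drop(G %*% gamma)            # X c at the rows
  a <- sum(system$v * system$z * (system$y - fitted_core)) /
       sum(system$v * system$z^2)
  list(gamma = gamma, intercept = a,
       fitted = fitted_core + system$z * a, G = G)
}

#' Weighted ridge fit of the stacked system at a fixed penalty
#'
#' Minimizes `sum_j (w_j / n_j) sum_i residual^2 + lambda ||c||^2` with an
#' unpenalized intercept.  `method = "primal"` solves the normal equations in
#' the feature dimension; `"dual"` solves in the row dimension through the
#' factorized Gram matrix; `"auto"` picks primal when the total feature
#' dimension is at most the row count.  Both paths compute the same solution.
#'
#' @param system an [assemble_system()] object.
#' @param lambda penalty `>= 0` (`> 0` required if the design is rank
#'   deficient).
#' @param method `"auto"`, `"primal"` or `"dual"`.
#' @return list with `coef` (primal; `(p+1) D` vector) or `gamma` (dual row
#'   weights), `intercept`, and `fitted` values on the stacked rows.
#' @export
ridge_fit <- function(system, lambda, method = c("auto", "primal", "dual")) {
  stopifnot(inherits(system, "grad_system"), lambda >= 0)
  method <- match.arg(method)
  if (method == "auto")
    method <- if (system$D_total <= system$N) "primal" else "dual"
  if (method == "primal") .solve_primal(system, lambda)
  else .solve_dual(system, lambda)
}

## Spectral factorization of the projected, weighted system used by GCV.
## Returns eigenvalues e_i of the projected Gram (equivalently squared
## singular values of the projected design) and the machinery to produce
## fitted values for any lambda.
.gcv_factor <- function(system, method = c("auto", "primal", "dual")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (system$D_total <= system$N) "primal" else "dual"
  sc <- .sys_scaled(system)
  zb <- sc$zt / sqrt(sc$zn2)
  if (method == "primal") {
    X <- .design_matrix(system$basis, system$T, system$kinds, system$p)
    Xt <- X * sc$sv
    Xp <- Xt - zb %o% drop(crossprod(zb, Xt))
    sv <- svd(Xp, nu = min(dim(Xp)), nv = 0)
    U <- sv$u; e <- sv$d^2
    extra <- list(X = X)
  } else {
    G <- factorized_gram(system$basis, system$T, system$kinds, system$p)
    Gt <- G * tcrossprod(sc$sv)
    Gp <- Gt - zb %o% drop(crossprod(zb, Gt))
    Gp <- Gp - drop(Gp %*% zb) %o% zb
    Gp <- (Gp + t(Gp)) / 2
    ee <- eigen(Gp, symmetric = TRUE)
    ## clip the (numerically) negative tail but keep every mode: dropping
    ## small eigenvalues would bias the influence fit by O(e / lambda)
    U <- ee$vectors; e <- pmax(ee$values, 0)
    extra <- list(G = G)
  }
  yp <- sc$yt - zb * sum(zb * sc$yt)
  uy <- drop(crossprod(U, yp))
  hz <- zb * sum(zb * sc$yt)                   # intercept part of fitted
  list(method = method, U = U, e = e, uy = uy, hz = hz, sc = sc, extra = extra)
}

.gcv_eval <- function(fac, system, lambda) {
  shr <- fac$e / (fac$e + lambda)
  fit_t <- fac$hz + drop(fac$U %*% (shr * fac$uy))
  yhat <- fit_t / fac$sc$sv
  trA <- 1 + sum(shr)
  rss <- sum((yhat - system$y)^2)
  N <- system$N
  list(gcv = rss / ((N - trA) / N)^2, trace = trA, yhat = yhat, rss = rss)
}

#' Generalized cross-validation over a penalty grid
#'
#' For each `lambda` computes the influence fit `yhat = A(lambda) y` on the
#' stacked weighted system and the criterion
#' `GCV(lambda) = ||yhat - y||^2 / [N^{-1} tr(I - A(lambda))]^2`
#' with `N` the total row count, using an exact spectral factorization of the
#' solve (so the influence trace is exact).  Ties are broken toward the
#' larger (smoother) penalty.
#'
#' @param system an [assemble_system()] object.
#' @param lambda_grid positive penalties to score.
#' @param method solver path, as in [ridge_fit()].
#' @return list with `lambda` (the minimizer), `grid`, `gcv`, `trace`, and
#'   `yhat` at the minimizer.
#' @export
gcv_select <- function(system, lambda_grid, method = c("auto", "primal", "dual")) {
  stopifnot(inherits(system, "grad_system"), length(lambda_grid) >= 1,
            all(lambda_grid > 0))
  lambda_grid <- sort(as.numeric(lambda_grid))
  fac <- .gcv_factor(system, match.arg(method))
  vals <- traces <- numeric(length(lambda_grid))
  best <- NULL
  for (i in seq_along(lambda_grid)) {
    ev <- .gcv_eval(fac, system, lambda_grid[i])
    vals[i] <- ev$gcv; traces[i] <- ev$trace
  }
  if (all(!is.finite(vals))) stop("GCV criterion non-finite on the whole grid")
  ok <- which(is.finite(vals))
  i_best <- max(ok[vals[ok] <= min(vals[ok]) * (1 + 1e-12)])
  ev <- .gcv_eval(fac, system, lambda_grid[i_best])
  list(lambda = lambda_grid[i_best], grid = lambda_grid, gcv = vals,
       trace = traces, yhat = ev$yhat, factor = fac)
}

.default_lambda_grid <- function() exp(seq(log(1e-8), log(10), length.out = 50))

## ---- main fitting function --------------------------------------------

#' Fit the gradient-augmented SS-ANOVA random-feature model
#'
#' Builds a random Fourier feature basis for the chosen shift-invariant
#' kernel, assembles the derivative-augmented weighted least-squares system
#' from function and gradient channels, selects the ridge penalty by
#' generalized cross-validation, and returns a fitted model that can be
#' evaluated (and differentiated) anywhere in the domain.
#'
#' The number of features per coordinate defaults to `n0 / 10` rounded up
#' (at least 5), where `n0` is the channel-0 sample size.  Kernel scales
#' refer to unit-cube coordinates; `scales = "cv"` selects a common scale by
#' k-fold cross-validation over `scale_grid`.
#'
#' @param data a [gradient_data()] object.
#' @param kernel kernel family name or a [kernel_spec()].
#' @param scales numeric scale(s) in unit-cube coordinates, or `"cv"`.
#' @param s features per coordinate (`NULL` for the default rule).
#' @param r interaction order (default `d`, full interaction).
#' @param lambda penalty grid (`NULL` for 50 log-spaced values in
#'   `[1e-8, 10]`), or a single value to skip selection.
#' @param weights `p` channel weights (`NULL`: from known variances if
#'   present, else the difference-based estimate).
#' @param seed master seed; basis and any randomness derive child seeds from
#'   it, so refits are bitwise reproducible.
#' @param method solver path, as in [ridge_fit()].
#' @param scale_grid candidate scales for `scales = "cv"`.
#' @param cv_folds folds for scale cross-validation.
#' @return an object of class `gradspline`.
#' @examples
#' set.seed(1)
#' T0 <- matrix(runif(60), 20, 3)
#' dat <- gradient_data(list(T0), list(sin(2 * pi * T0[, 1]) + rnorm(20, 0, .1)))
#' fit <- gradspline(dat, s = 8, seed = 1)
#' predict(fit, matrix(0.5, 1, 3))
#' @export
gradspline <- function(data, kernel = "matern52", scales = 0.5, s = NULL,
                       r = NULL, lambda = NULL, weights = NULL, seed = 1L,
                       method = c("auto", "primal", "dual"),
                       scale_grid = exp(seq(log(0.1), log(2), length.out = 8)),
                       cv_folds = 5L) {
  stopifnot(inherits(data, "gradient_data"))
  method <- match.arg(method)
  d <- data$d; p <- data$p
  r <- as.integer(r %||% d)
  n0 <- data$n[1]
  s <- as.integer(s %||% max(5L, ceiling(n0 / 10)))
  seeds <- .child_seeds(seed, 2L)
  if (identical(scales, "cv")) {
    scales <- .cv_scales(data, kernel, s, r, scale_grid, cv_folds,
                         weights = weights, seed = seeds[2], method = method)
  }
  kspec <- if (inherits(kernel, "kernel_spec")) kernel
           else kernel_spec(kernel, scales, d)
  if (p > 0L && !.kernel_differentiable(kspec)) .stop_nondiff(kspec)
  weights <- weights %||% if (p > 0L) estimate_weights(data) else numeric(0)
  basis <- build_basis(d, s, r, kspec, seeds[1])
  system <- assemble_system(data, basis, weights)
  grid <- if (is.null(lambda)) .default_lambda_grid() else as.numeric(lambda)
  sel <- gcv_select(system, grid, method = method)
  solved <- if (sel$factor$method == "primal")
    .solve_primal(system, sel$lambda, X = sel$factor$extra$X)
  else
    .solve_dual(system, sel$lambda, G = sel$factor$extra$G)
  cvec <- solved$coef
  if (is.null(cvec) && system$D_total <= 2e6)
    cvec <- .dual_to_coef(basis, system$T, system$kinds, p, solved$gamma)
  structure(list(basis = basis, kernel = kspec, domain = data$domain,
                 d = d, p = p, s = s, r = r,
                 coefficients = cvec, intercept = solved$intercept,
                 gamma = solved$gamma, system = system,
                 lambda = sel$lambda,
                 gcv = data.frame(lambda = sel$grid, gcv = sel$gcv,
                                  trace = sel$trace),
                 weights = weights, seed = as.integer(seed),
                 n = data$n, solver = sel$factor$method,
                 fitted_rows = solved$fitted,
                 call = match.call()),
            class = "gradspline")
}

## common-scale selection by k-fold CV on the weighted objective; `data` may
## be a single dataset or a list of replicate datasets whose CV scores are
## pooled (pooling shrinks the selection noise of a single replicate)
.cv_scales <- function(data, kernel, s, r, scale_grid, folds, weights, seed,
                       method = "auto") {
  datasets <- if (inherits(data, "gradient_data")) list(data) else data
  seeds <- .child_seeds(seed, 2L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seeds[1])
  fold_ids <- lapply(datasets, function(dd)
    lapply(dd$n, function(nj) sample(rep_len(seq_len(folds), nj))))
  score <- numeric(length(scale_grid))
  for (si in seq_along(scale_grid)) {
    sse <- 0
    for (di in seq_along(datasets)) {
      dd <- datasets[[di]]; p <- dd$p; fold_id <- fold_ids[[di]]
      for (f in seq_len(folds)) {
        tr_des <- list(); tr_res <- list()
        for (jc in 0:p) {
          keep <- fold_id[[jc + 1L]] != f
          if (sum(keep) < 2) { keep[] <- TRUE }
          tr_des[[jc + 1L]] <- dd$designs[[jc + 1L]][keep, , drop = FALSE]
          tr_res[[jc + 1L]] <- dd$responses[[jc + 1L]][keep]
        }
        dtr <- gradient_data(tr_des, tr_res, d = dd$d, sigma2 = dd$sigma2,
                             domain = dd$domain)
        ft <- gradspline(dtr, kernel = kernel, scales = scale_grid[si], s = s,
                         r = r, weights = weights, seed = seeds[2],
                         method = method)
        for (jc in 0:p) {
          ho <- fold_id[[jc + 1L]] == f
          if (!any(ho)) next
          Th <- dd$designs[[jc + 1L]][ho, , drop = FALSE]
          yh <- dd$responses[[jc + 1L]][ho]
          pr <- predict(ft, Th, gradient = if (jc > 0L) jc else NULL)
          wj <- if (jc == 0L) 1 else ft$weights[jc]
          sse <- sse + wj * mean((yh - pr)^2)
        }
      }
    }
    score[si] <- sse
  }
  scale_grid[which.min(score)]
}

#' Predict from a fitted gradient-augmented model
#'
#' Evaluates the fitted function, or one of its partial derivatives
#' (`gradient = j`, any `j` in `1..d`, computed analytically from the feature
#' expansion), at new design points.
#'
#' @param object a [gradspline()] fit.
#' @param newdata matrix (or data frame) of points, `m x d`, in original
#'   (domain-box) coordinates.
#' @param gradient `NULL` for function values, or a coordinate index.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gradspline <- function(object, newdata, gradient = NULL, ...) {
  Tn <- as.matrix(newdata)
  if (ncol(Tn) != object$d) stop("newdata must have ", object$d, " columns")
  Tu <- .to_unit(Tn, object$domain)
  deriv <- as.integer(gradient %||% 0L)
  if (deriv < 0L || deriv > object$d) stop("gradient coordinate outside 1..d")
  if (!is.null(object$coefficients)) {
    val <- .contract_predict(object$basis, object$coefficients, Tu,
                             deriv = deriv, p = object$p)
  } else {
    K <- .rf_cross_gram(object$basis, Tu, rep(deriv, nrow(Tu)),
                        object$system$T, object$system$kinds, object$p)
    val <- drop(K %*% object$gamma)
  }
  if (deriv == 0L) val + object$intercept
  else val / .box_widths(object$domain)[deriv]
}

#' @export
print.gradspline <- function(x, ...) {
  cat("Gradient-augmented SS-ANOVA random-feature fit\n")
  cat(sprintf("  d = %d, p = %d, interaction order r = %d, s = %d (D = %d)\n",
              x$d, x$p, x$r, x$s, x$basis$D))
  cat(sprintf("  kernel = %s, scales = %s\n", x$kernel$family,
              paste(signif(x$kernel$scales, 3), collapse = ", ")))
  cat(sprintf("  lambda (GCV) = %.3g, solver = %s\n", x$lambda, x$solver))
  if (x$p > 0)
    cat("  channel weights:", paste(signif(x$weights, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.gradspline <- function(object, ...) {
  res <- residuals(object)
  out <- list(model = object,
              rss_by_channel = vapply(split(res, object$system$kinds),
                                      function(r) mean(r^2), numeric(1)),
              lambda = object$lambda,
              gcv_min = min(object$gcv$gcv),
              edf = object$gcv$trace[which.min(abs(object$gcv$lambda -
                                                   object$lambda))])
  class(out) <- "summary.gradspline"
  out
}

#' @export
print.summary.gradspline <- function(x, ...) {
  print(x$model)
  cat(sprintf("  effective df (tr A) = %.2f, min GCV = %.4g\n", x$edf, x$gcv_min))
  cat("  training MSE by channel:",
      paste(sprintf("%s: %.4g", names(x$rss_by_channel), x$rss_by_channel),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.gradspline <- function(object, ...) {
  cvec <- object$coefficients
  if (is.null(cvec))
    cvec <- .dual_to_coef(object$basis, object$system$T, object$system$kinds,
                          object$p, object$gamma)
  D <- object$basis$D
  out <- lapply(0:object$p, function(l) cvec[l * D + seq_len(D)])
  names(out) <- paste0("c", 0:object$p)
  c(out, list(intercept = object$intercept))
}

#' @export
fitted.gradspline <- function(object, ...) object$fitted_rows

#' @export
residuals.gradspline <- function(object, ...) object$system$y - object$fitted_rows

#' @export
plot.gradspline <- function(x, ...) {
  plot(x$gcv$lambda, x$gcv$gcv, log = "xy", type = "b", pch = 16, cex = 0.6,
       xlab = expression(lambda), ylab = "GCV", ...)
  graphics::abline(v = x$lambda, lty = 2)
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Stores the basis, coefficients (or dual weights with their rows), penalty,
#' weights and domain so predictions can be replayed exactly.
#'
#' @param model a [gradspline()] fit.
#' @param path output file.
#' @export
write_gradspline <- function(model, path) {
  obj <- list(kernel = list(family = model$kernel$family,
                            scales = model$kernel$scales),
              d = model$d, p = model$p, s = model$s, r = model$r,
              seed = model$seed, basis_seed = model$basis$seed,
              omega = model$basis$omega, phase = model$basis$phase,
              domain = model$domain, lambda = model$lambda,
              weights = model$weights, intercept = model$intercept,
              coefficients = model$coefficients,
              gamma = model$gamma,
              train_T = model$system$T, train_kinds = model$system$kinds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a fitted model written by [write_gradspline()]
#'
#' @param path JSON file path.
#' @return a `gradspline` object (prediction-capable).
#' @export
read_gradspline <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  ks <- kernel_spec(o$kernel$family, as.numeric(o$kernel$scales), o$d)
  basis <- build_basis(o$d, o$s, o$r, ks, o$basis_seed)
  basis$omega <- matrix(as.numeric(o$omega), o$d, o$s)
  basis$phase <- matrix(as.numeric(o$phase), o$d, o$s)
  structure(list(basis = basis, kernel = ks,
                 domain = matrix(as.numeric(o$domain), 2, o$d),
                 d = o$d, p = o$p, s = o$s, r = o$r,
                 coefficients = if (length(o$coefficients)) as.numeric(o$coefficients),
                 intercept = as.numeric(o$intercept),
                 gamma = if (length(o$gamma)) as.numeric(o$gamma),
                 system = list(T = matrix(as.numeric(o$train_T), ncol = o$d),
                               kinds = as.integer(o$train_kinds)),
                 lambda = as.numeric(o$lambda),
                 weights = as.numeric(o$weights), seed = o$seed,
                 solver = "restored"),
            class = "gradspline")
}
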