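#' Stochastic kriging on function data
#'
#' Gaussian-process mean-response metamodel for a stochastic simulation,
#' using the plain tensor-product kernel (default Matern-5/2) and a noise
#' nugget: solves `(G + nugget I) beta = y - mu` with a constant mean `mu`
#' estimated jointly (ordinary-kriging style) or fixed at zero.  A common
#' lengthscale for all coordinates (in unit-cube units) is chosen by k-fold
#' cross-validation over `scale_grid`.
#'
#' @param x `n x d` design matrix (function-channel data only), or a
#'   [gradient_data()] whose channel 0 is used.
#' @param y responses (ignored when `x` is a `gradient_data`).
#' @param kernel kernel family name.
#' @param scale_grid candidate lengthscales; default 8 log-spaced values in
#'   `[0.1, 2]`.
#' @param nugget noise variance of the (averaged) responses: a scalar, or a
#'   vector with one value per design point (the stochastic-kriging
#'   convention, reflecting heteroscedastic simulation noise); `NULL` takes
#'   the per-point variances recorded by the simulator when available, else
#'   estimates a common value by the nearest-neighbour difference estimator.
#' @param folds cross-validation folds.
#' @param seed seed controlling the fold assignment.
#' @param mean `"constant"` (estimated) or `"zero"`.
#' @param anisotropic after the shared-scale search, refine per-coordinate
#'   lengthscales by greedy coordinate descent over the same grid.
#' @param scales fixed per-coordinate lengthscales; when given, the
#'   cross-validation search is skipped entirely.
#' @param amplitude process variance of the GP prior (the kernel is scaled
#'   `amplitude * K` with `K(0) = 1`); `NULL` uses a moment estimate,
#'   `var(y)` minus the mean nugget.
#' @param domain `2 x d` design box (default unit cube; taken from the
#'   dataset when one is supplied).
#' @return an object of class `stochkrig`.
#' @export
sk_fit <- function(x, y = NULL, kernel = "matern52",
                   scale_grid = exp(seq(log(0.1), log(2), length.out = 8)),
                   nugget = NULL, folds = 5L, seed = 1L,
                   mean = c("constant", "zero"), domain = NULL,
                   anisotropic = TRUE, scales = NULL, amplitude = NULL) {
  mean <- match.arg(mean)
  if (inherits(x, "gradient_data")) {
    domain <- domain %||% x$domain
    if (is.null(nugget)) {
      pv <- attr(x, "pointvar")
      nugget <- if (!is.null(pv)) pv[[1]]
                else if (!is.null(x$sigma2)) x$sigma2[1]
    }
    y <- x$responses[[1]]
    x <- x$designs[[1]]
  }
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x); d <- ncol(x)
  stopifnot(length(y) == n, n >= 2)
  domain <- domain %||% .default_domain(d)
  Tu <- .to_unit(x, domain)
  if (is.null(nugget)) {
    pc1 <- if (d == 1L) Tu[, 1] else stats::prcomp(Tu)$x[, 1]
    ys <- y[order(pc1)]
    nugget <- sum(diff(ys)^2) / (2 * (n - 1))
  }
  if (any(nugget < 0)) stop("nugget must be >= 0")
  if (!length(nugget) %in% c(1L, n)) stop("nugget must be scalar or one per point")
  nug <- rep_len(nugget, n)
  ## process variance (kernel amplitude) by moments: the kernel has K(0) = 1,
  ## so rescale the nugget relative to the signal variance of the responses
  amp <- amplitude %||%
    max(stats::var(y) - mean(nug), 0.05 * stats::var(y), 1e-12)
  nug <- nug / amp
  gram <- function(T1, T2, tau) {
    tau <- rep_len(tau, d)
    G <- 1
    for (j in seq_len(d))
      G <- G * .kderiv(kernel, tau[j], outer(T1[, j], T2[, j], "-"), 0L)
    G
  }
  solve_k <- function(G, yv, nv) {
    Gn <- G; diag(Gn) <- diag(Gn) + pmax(nv, 1e-12)
    ch <- tryCatch(chol(Gn), error = function(e)
      stop("singular kriging system; increase the nugget"))
    ginv <- function(b) backsolve(ch, backsolve(ch, b, transpose = TRUE))
    if (mean == "constant") {
      one <- rep(1, length(yv))
      mu <- sum(ginv(yv)) / sum(ginv(one))
    } else mu <- 0
    list(beta = ginv(yv - mu), mu = mu)
  }
  ## k-fold CV score for a lengthscale vector
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  fold_id <- sample(rep_len(seq_len(folds), n))
  cv_score <- function(tau) {
    sse <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (sum(tr) < 2 || all(tr)) next
      G <- gram(Tu[tr, , drop = FALSE], Tu[tr, , drop = FALSE], tau)
      sol <- solve_k(G, y[tr], nug[tr])
      Kc <- gram(Tu[!tr, , drop = FALSE], Tu[tr, , drop = FALSE], tau)
      sse <- sse + sum((y[!tr] - (sol$mu + Kc %*% sol$beta))^2)
    }
    sse
  }
  if (!is.null(scales)) {
    tau <- rep_len(scales, d)
    cv <- NA_real_
    scale_grid <- tau
  } else {
  cv <- vapply(scale_grid, function(tau) cv_score(rep(tau, d)), numeric(1))
  tau <- rep(scale_grid[which.min(cv)], d)
  best <- min(cv)
  if (anisotropic && length(scale_grid) > 1L) {
    ## greedy coordinate descent over the grid, two sweeps
    for (sweep_i in 1:2) for (j in seq_len(d)) {
      sc <- vapply(scale_grid, function(tj) {
        tt <- tau; tt[j] <- tj; cv_score(tt)
      }, numeric(1))
      if (min(sc) < best) { best <- min(sc); tau[j] <- scale_grid[which.min(sc)] }
    }
  }
  }
  sol <- solve_k(gram(Tu, Tu, tau), y, nug)
  structure(list(kernel = kernel, tau = tau, nugget = nugget, amplitude = amp,
                 d = d,
                 domain = domain, T = Tu, beta = sol$beta, mu = sol$mu,
                 mean = mean, cv = data.frame(scale = scale_grid, sse = cv),
                 folds = folds,
                 seed = as.integer(seed)),
            class = "stochkrig")
}

#' @export
print.stochkrig <- function(x, ...) {
  cat(sprintf(
    "stochastic kriging: d = %d, n = %d, lengthscales = %s, mean nugget = %.3g, mean = %s\n",
    x$d, length(x$beta), paste(signif(x$tau, 3), collapse = ", "),
    mean(x$nugget), x$mean))
  invisible(x)
}

#' Kriging mean prediction
#'
#' @param object an [sk_fit()] model.
#' @param newdata `m x d` matrix in original coordinates.
#' @param ... unused.
#' @return numeric vector of posterior-mean predictions.
#' @export
predict.stochkrig <- function(object, newdata, ...) {
  Tn <- .to_unit(as.matrix(newdata), object$domain)
  G <- 1
  tau <- rep_len(object$tau, object$d)
  for (j in seq_len(object$d))
    G <- G * .kderiv(object$kernel, tau[j],
                     outer(Tn[, j], object$T[, j], "-"), 0L)
  drop(object$mu + G %*% object$beta)
}
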