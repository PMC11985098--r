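## Exact kernel-representer solver, used as a small-sample oracle for
## validating the random-feature approximation.  The fitted function lies in
## the span of kernel sections at the function-data points and derivative
## sections at the gradient-data points; the SS-ANOVA kernel truncated at
## interaction order r,
##   K_r(t, t') = sum_{blocks B, |B| <= r} prod_{j in B} K(t_j - t'_j),
## matches the hypothesis space of the random-feature expansion.

## Cross Gram of representer functionals: entry (u, m) applies derivative
## order a = e_{kind1[u]} to the first argument and b = e_{kind2[m]} to the
## second argument of K_r.
.kernel_cross_gram <- function(kspec, blocks, T1, kinds1, T2, kinds2) {
  d <- kspec$d
  T1 <- as.matrix(T1); T2 <- as.matrix(T2)
  kinds1 <- as.integer(kinds1); kinds2 <- as.integer(kinds2)
  if (!.kernel_differentiable(kspec) && (any(kinds1 > 0L) || any(kinds2 > 0L)))
    .stop_nondiff(kspec)
  res <- matrix(0, nrow(T1), nrow(T2))
  for (k1 in unique(kinds1)) {
    idx1 <- which(kinds1 == k1)
    for (k2 in unique(kinds2)) {
      idx2 <- which(kinds2 == k2)
      Fc <- new.env(parent = emptyenv())
      getF <- function(j, a, b) {
        key <- paste0(j, "_", a, "_", b)
        if (is.null(Fc[[key]])) {
          U <- outer(T1[idx1, j], T2[idx2, j], "-")
          Fc[[key]] <- (-1)^b * .kderiv(kspec$family, kspec$scales[j], U, a + b)
        }
        Fc[[key]]
      }
      a <- integer(d); b <- integer(d)
      if (k1 > 0L) a[k1] <- 1L
      if (k2 > 0L) b[k2] <- 1L
      req <- which(a > 0L | b > 0L)
      acc <- matrix(0, length(idx1), length(idx2))
      for (B in blocks) {
        if (!all(req %in% B)) next
        M <- getF(B[1], a[B[1]], b[B[1]])
        for (j in B[-1]) M <- M * getF(j, a[j], b[j])
        acc <- acc + M
      }
      res[idx1, idx2] <- acc
    }
  }
  res
}

#' Exact kernel-representer fit (small-sample oracle)
#'
#' Solves the penalized gradient-augmented regression exactly in the
#' finite-dimensional representer span: kernel sections at the function-data
#' points plus derivative sections at the gradient-data points, under the
#' ANOVA kernel truncated at interaction order `r`.  The objective is the
#' same per-channel weighted loss as the random-feature estimator plus
#' `lambda` times the squared RKHS norm, so the two solutions coincide as the
#' number of random features grows.
#'
#' Intended for validation at small `N` (a guard rejects `N > 2000`); the
#' solve is `O(N^3)`.  A symmetric jitter of `1e-10 * mean(diag(Q))` is added
#' to the representer Gram for conditioning.
#'
#' @param data a [gradient_data()] object.
#' @param kernel kernel family name or [kernel_spec()] (laplacian is rejected
#'   when gradient channels are present).
#' @param lambda penalty `> 0`.
#' @param weights `p` channel weights (default: from variances, as in
#'   [estimate_weights()]).
#' @param r interaction order of the ANOVA kernel (default `d`).
#' @param intercept add an unpenalized constant term (default `FALSE`,
#'   matching the bare representer expansion; set `TRUE` when comparing with
#'   a [gradspline()] fit, which always has one).
#' @param scales kernel scales when `kernel` is a family name.
#' @param edf instead of `lambda`, target effective degrees of freedom (the
#'   influence-matrix trace); the penalty is then solved for by root finding.
#'   The natural way to put the exact solver and the random-feature fit at
#'   the same smoothness, since their penalties (RKHS norm vs coefficient
#'   L2 norm) are not on a common scale.
#' @return an object of class `gradoracle`.
#' @export
oracle_fit <- function(data, kernel = "matern52", lambda = NULL, weights = NULL,
                       r = NULL, intercept = FALSE, scales = 0.5, edf = NULL) {
  stopifnot(inherits(data, "gradient_data"))
  if (is.null(lambda) && is.null(edf)) stop("supply lambda or edf")
  if (!is.null(lambda)) stopifnot(lambda > 0)
  d <- data$d; p <- data$p
  r <- as.integer(r %||% d)
  kspec <- if (inherits(kernel, "kernel_spec")) kernel
           else kernel_spec(kernel, scales, d)
  if (p > 0L && !.kernel_differentiable(kspec)) .stop_nondiff(kspec)
  N <- sum(data$n)
  if (N > 2000L) stop("oracle solver is guarded to N <= 2000 rows (got ", N, ")")
  weights <- weights %||% if (p > 0L) estimate_weights(data) else numeric(0)
  wid <- .box_widths(data$domain)
  Tl <- list(); yl <- list(); kl <- list(); vl <- list()
  for (jc in 0:p) {
    Tu <- .to_unit(data$designs[[jc + 1L]], data$domain)
    yj <- data$responses[[jc + 1L]]
    if (jc > 0L) yj <- yj * wid[jc]
    nj <- nrow(Tu)
    w <- if (jc == 0L) 1 else weights[jc] / wid[jc]^2
    Tl[[jc + 1L]] <- Tu; yl[[jc + 1L]] <- yj
    kl[[jc + 1L]] <- rep(jc, nj); vl[[jc + 1L]] <- rep(w / nj, nj)
  }
  T <- do.call(rbind, Tl); y <- unlist(yl)
  kinds <- unlist(kl); v <- unlist(vl)
  blocks <- .anova_blocks(d, r)
  Q <- .kernel_cross_gram(kspec, blocks, T, kinds, T, kinds)
  Q <- (Q + t(Q)) / 2
  jit <- 1e-10 * mean(diag(Q))
  diag(Q) <- diag(Q) + jit
  z <- as.numeric(kinds == 0L)
  if (is.null(lambda)) {
    trace_at <- function(lam) .oracle_trace(Q, v, z, lam, intercept)
    f <- function(loglam) trace_at(exp(loglam)) - edf
    lo <- log(1e-10); hi <- log(1e4)
    if (f(lo) < 0 || f(hi) > 0)
      stop("requested edf outside the attainable range")
    lambda <- exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
  }
  if (intercept) {
    A <- rbind(cbind(v * Q + diag(lambda, N), v * z),
               c(crossprod(z, v * Q), sum(v * z^2)))
    rhs <- c(v * y, sum(z * v * y))
    sol <- solve(A, rhs)
    alpha <- sol[seq_len(N)]; a0 <- sol[N + 1L]
  } else {
    alpha <- solve(v * Q + diag(lambda, N), v * y)
    a0 <- 0
  }
  structure(list(kernel = kspec, blocks = blocks, r = r, d = d, p = p,
                 T = T, kinds = kinds, y = y, v = v,
                 alpha = alpha, intercept = a0, has_intercept = intercept,
                 lambda = lambda, weights = weights, jitter = jit,
                 domain = data$domain, Q = Q),
            class = "gradoracle")
}

#' @export
print.gradoracle <- function(x, ...) {
  cat(sprintf(
    "kernel-representer oracle: d = %d, p = %d, r = %d, N = %d, lambda = %.3g\n",
    x$d, x$p, x$r, length(x$alpha), x$lambda))
  invisible(x)
}

#' Predict from the kernel oracle
#'
#' @param object an [oracle_fit()] model.
#' @param newdata `m x d` matrix in original coordinates.
#' @param gradient `NULL` for function values or a coordinate index for the
#'   analytic partial derivative.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.gradoracle <- function(object, newdata, gradient = NULL, ...) {
  Tn <- as.matrix(newdata)
  if (ncol(Tn) != object$d) stop("newdata must have ", object$d, " columns")
  Tu <- .to_unit(Tn, object$domain)
  deriv <- as.integer(gradient %||% 0L)
  if (deriv < 0L || deriv > object$d) stop("gradient coordinate outside 1..d")
  ## evaluation applies derivative `deriv` to the second kernel argument;
  ## transpose roles so rows are prediction functionals
  K <- .kernel_cross_gram(object$kernel, object$blocks,
                          Tu, rep(deriv, nrow(Tu)), object$T, object$kinds)
  val <- drop(K %*% object$alpha)
  if (deriv == 0L) val + object$intercept
  else val / .box_widths(object$domain)[deriv]
}

#' @rdname predict.gradoracle
#' @param model an [oracle_fit()] model.
#' @param t a single point (length-`d` vector) or `m x d` matrix.
#' @export
oracle_predict <- function(model, t) {
  predict(model, if (is.null(dim(t))) matrix(t, nrow = 1) else t)
}

#' @rdname predict.gradoracle
#' @param j gradient coordinate.
#' @export
oracle_predict_gradient <- function(model, t, j) {
  predict(model, if (is.null(dim(t))) matrix(t, nrow = 1) else t, gradient = j)
}

## influence-matrix trace of the oracle smoother at penalty lam
.oracle_trace <- function(Q, v, z, lam, intercept) {
  N <- nrow(Q)
  if (intercept) {
    K <- rbind(cbind(v * Q + diag(lam, N), v * z),
               c(crossprod(z, v * Q), sum(v * z^2)))
    B <- rbind(diag(v, N), z * v)
    sum(diag(cbind(Q, z) %*% solve(K, B)))
  } else {
    sum(diag(Q %*% solve(v * Q + diag(lam, N), diag(v, N))))
  }
}

#' Influence trace (effective degrees of freedom) of an oracle fit
#'
#' @param model an [oracle_fit()] object.
#' @return the trace of the influence matrix at the model's penalty.
#' @export
oracle_edf <- function(model) {
  .oracle_trace(model$Q, model$v, as.numeric(model$kinds == 0L),
                model$lambda, model$has_intercept)
}

## penalized objective of a coefficient vector in an (extended) section span;
## used by tests of representer sufficiency
.oracle_objective <- function(model, alpha = model$alpha, Q = model$Q,
                              Qdata = NULL) {
  Qdata <- Qdata %||% Q
  fit <- drop(Qdata %*% alpha) + model$intercept
  sum(model$v * (model$y - fit)^2) + model$lambda * drop(crossprod(alpha, Q %*% alpha))
}
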