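#' Shift-invariant kernel specification
#'
#' Defines the univariate kernel family and per-coordinate scale parameters
#' used to build the tensor-product SS-ANOVA kernel and its Bochner spectral
#' density.  Kernels are evaluated with the convention `K(0) = 1`; the
#' integrate-to-one normalization required by Bochner's theorem is absorbed
#' into the spectral density, so that estimates are invariant to kernel scale.
#'
#' Supported families (displacement `u`, scale `tau`):
#' \describe{
#'   \item{matern52}{`(1 + |u|/tau + u^2/(3 tau^2)) exp(-|u|/tau)`, a Matern
#'     kernel with smoothness 5/2 and lengthscale `sqrt(5) tau`.  Twice
#'     continuously differentiable, so derivative observations are supported.}
#'   \item{gaussian}{`exp(-tau^2 u^2 / 2)` (note `tau` is an inverse length).}
#'   \item{laplacian}{`exp(-|u|/tau)`.  Not differentiable at the origin; any
#'     derivative request under this family is an error, and it is admitted
#'     only for function-only fitting (`p = 0`).}
#'   \item{cauchy}{`1 / (1 + tau^2 u^2)`.}
#' }
#'
#' @param family one of `"matern52"`, `"gaussian"`, `"laplacian"`, `"cauchy"`.
#' @param scales positive scale parameters, recycled to length `d`.
#' @param d dimension (number of coordinates).
#' @return an object of class `kernel_spec`.
#' @examples
#' ks <- kernel_spec("matern52", scales = 0.5, d = 3)
#' kernel_eval(ks, 1, 0.2)
#' @export
kernel_spec <- function(family = c("matern52", "gaussian", "laplacian", "cauchy"),
                        scales = 0.5, d = length(scales)) {
  family <- match.arg(family)
  stopifnot(is.numeric(scales), length(scales) >= 1, d >= 1)
  scales <- rep_len(as.numeric(scales), d)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("all kernel scales must be finite and > 0")
  structure(list(family = family, scales = scales, d = as.integer(d)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("kernel_spec: %s, d = %d, scales = %s\n", x$family, x$d,
              paste(signif(x$scales, 4), collapse = ", ")))
  invisible(x)
}

.check_kernel_spec <- function(spec) {
  if (!inherits(spec, "kernel_spec")) stop("'spec' must be a kernel_spec")
  spec
}

.kernel_differentiable <- function(spec) spec$family != "laplacian"

.stop_nondiff <- function(spec) {
  stop("kernel family '", spec$family,
       "' is not differentiable at the origin; derivatives are unavailable")
}

## Univariate kernel and its derivatives in the displacement, K(0) = 1.
## order 0, 1, 2; matern52 is C^2, gaussian/cauchy are smooth.
.kderiv <- function(family, tau, u, order = 0L) {
  a <- abs(u)
  switch(family,
    matern52 = {
      e <- exp(-a / tau)
      switch(as.character(order),
        "0" = (1 + a / tau + a^2 / (3 * tau^2)) * e,
        "1" = -(u / (3 * tau^2)) * (1 + a / tau) * e,
        "2" = -(1 / (3 * tau^2)) * (1 + a / tau - a^2 / tau^2) * e,
        stop("unsupported derivative order ", order))
    },
    gaussian = {
      e <- exp(-tau^2 * u^2 / 2)
      switch(as.character(order),
        "0" = e,
        "1" = -tau^2 * u * e,
        "2" = (tau^4 * u^2 - tau^2) * e,
        stop("unsupported derivative order ", order))
    },
    laplacian = {
      if (order > 0) stop("laplacian kernel is not differentiable")
      exp(-a / tau)
    },
    cauchy = {
      den <- 1 + tau^2 * u^2
      switch(as.character(order),
        "0" = 1 / den,
        "1" = -2 * tau^2 * u / den^2,
        "2" = -2 * tau^2 * (1 - 3 * tau^2 * u^2) / den^3,
        stop("unsupported derivative order ", order))
    },
    stop("unknown kernel family ", family))
}

#' Evaluate the univariate kernel for one coordinate
#'
#' @param spec a [kernel_spec()].
#' @param j coordinate index in `1..d`.
#' @param u displacement(s) `t - t'` (vectorized).
#' @return kernel value(s) with `K(0) = 1`.
#' @export
kernel_eval <- function(spec, j, u) {
  .check_kernel_spec(spec)
  j <- as.integer(j)
  if (j < 1L || j > spec$d) stop("coordinate index j out of range")
  .kderiv(spec$family, spec$scales[j], u, 0L)
}

#' Evaluate the tensor-product kernel
#'
#' `K_d(t, t2) = prod_j K(t_j - t2_j)` with the univariate kernel of each
#' coordinate.
#'
#' @param spec a [kernel_spec()].
#' @param t,t2 numeric vectors of length `d`.
#' @return scalar kernel value.
#' @export
product_kernel_eval <- function(spec, t, t2) {
  .check_kernel_spec(spec)
  if (length(t) != spec$d || length(t2) != spec$d)
    stop("t and t2 must have length d = ", spec$d)
  prod(vapply(seq_len(spec$d),
              function(j) .kderiv(spec$family, spec$scales[j], t[j] - t2[j], 0L),
              numeric(1)))
}

#' Mixed partial derivatives of the tensor-product kernel
#'
#' Computes `d^{|a|} d^{|b|} K_d(t, t2) / dt^a dt2^b` exactly, where `a`
#' (`order1`) and `b` (`order2`) are multi-indices over the first and second
#' argument with at most one derivative per coordinate per argument.  Each
#' coordinate factor is `(-1)^{b_j} K^{(a_j + b_j)}(t_j - t2_j)`.
#'
#' @param spec a [kernel_spec()]; the `laplacian` family is rejected.
#' @param t,t2 numeric vectors of length `d`.
#' @param order1,order2 non-negative integer multi-indices of length `d`,
#'   entries at most 1.
#' @return scalar derivative value.
#' @export
product_kernel_partial <- function(spec, t, t2, order1 = integer(spec$d),
                                   order2 = integer(spec$d)) {
  .check_kernel_spec(spec)
  d <- spec$d
  order1 <- rep_len(as.integer(order1), d)
  order2 <- rep_len(as.integer(order2), d)
  if (length(t) != d || length(t2) != d) stop("t and t2 must have length d")
  if (any(order1 < 0L) || any(order2 < 0L) || any(order1 > 1L) || any(order2 > 1L))
    stop("derivative order per coordinate per argument must be 0 or 1")
  if (any(order1 + order2 > 0L) && !.kernel_differentiable(spec))
    .stop_nondiff(spec)
  out <- 1
  for (j in seq_len(d)) {
    m <- order1[j] + order2[j]
    out <- out * (-1)^order2[j] *
      .kderiv(spec$family, spec$scales[j], t[j] - t2[j], m)
  }
  out
}

## Spectral densities paired with the K(0)=1 kernels: E[cos(w u)] under the
## density equals the kernel, i.e. the density is the normalized kernel's
## Fourier transform.
##   gaussian  K = exp(-tau^2 u^2/2)      -> w ~ Normal(0, sd = tau)
##   laplacian K = exp(-|u|/tau)          -> w ~ Cauchy(scale = 1/tau)
##   cauchy    K = 1/(1 + tau^2 u^2)      -> w ~ Laplace(scale = tau)
##   matern52  (1+|u|/tau+u^2/3tau^2)e^{-|u|/tau} -> w = T/(sqrt(5) tau),
##             T ~ Student-t(5)  (spectral density prop. to (1/tau^2+w^2)^{-3})

#' Spectral density of the normalized kernel
#'
#' Density of the frequency distribution whose characteristic function is the
#' `K(0) = 1` kernel of coordinate `j` (Bochner pairing).
#'
#' @param spec a [kernel_spec()].
#' @param j coordinate index.
#' @param w frequencies (vectorized).
#' @return density values.
#' @export
spectral_density <- function(spec, j, w) {
  .check_kernel_spec(spec)
  tau <- spec$scales[as.integer(j)]
  switch(spec$family,
    gaussian  = stats::dnorm(w, sd = tau),
    laplacian = stats::dcauchy(w, scale = 1 / tau),
    cauchy    = exp(-abs(w) / tau) / (2 * tau),
    matern52  = stats::dt(sqrt(5) * tau * w, df = 5) * sqrt(5) * tau)
}

#' Cumulative distribution of the spectral density
#'
#' @inheritParams spectral_density
#' @return CDF values; useful for distributional tests of sampled frequencies.
#' @export
spectral_cdf <- function(spec, j, w) {
  .check_kernel_spec(spec)
  tau <- spec$scales[as.integer(j)]
  switch(spec$family,
    gaussian  = stats::pnorm(w, sd = tau),
    laplacian = stats::pcauchy(w, scale = 1 / tau),
    cauchy    = ifelse(w < 0, 0.5 * exp(w / tau), 1 - 0.5 * exp(-w / tau)),
    matern52  = stats::pt(sqrt(5) * tau * w, df = 5))
}

#' Sample frequencies from the spectral density
#'
#' Draws i.i.d. frequencies for coordinate `j` from the spectral density of
#' the normalized kernel.  Sampling under the `laplacian` family is allowed
#' (its Cauchy spectral density is proper); only derivative use is blocked,
#' because the Cauchy law has no second moment and derivative features
#' `-w sin(.)` would have infinite variance.
#'
#' @param spec a [kernel_spec()].
#' @param j coordinate index.
#' @param s number of draws.
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of `s` frequencies.
#' @export
spectral_sample <- function(spec, j, s, seed = NULL) {
  .check_kernel_spec(spec)
  s <- as.integer(s)
  if (s < 1L) stop("s must be >= 1")
  tau <- spec$scales[as.integer(j)]
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  switch(spec$family,
    gaussian  = stats::rnorm(s, sd = tau),
    laplacian = stats::rcauchy(s, scale = 1 / tau),
    cauchy    = sample(c(-1, 1), s, replace = TRUE) * stats::rexp(s, rate = 1 / tau),
    matern52  = stats::rt(s, df = 5) / (sqrt(5) * tau))
}
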