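#' Build a random Fourier feature basis
#'
#' Samples, per coordinate, `s` frequencies from the kernel's spectral density
#' and `s` phases uniform on `[0, 2*pi)`, and fixes the ordered list of ANOVA
#' interaction blocks (all strictly increasing index tuples of size `1..r`,
#' ordered by size then lexicographically).  The block for a tuple of size `k`
#' contributes `s^k` feature coordinates via Kronecker products, so the total
#' feature dimension is `D = sum_k choose(d,k) s^k`.
#'
#' @param d dimension.
#' @param s features per coordinate (`>= 1`).
#' @param r interaction order, `1 <= r <= d`.
#' @param kernel a [kernel_spec()] with `kernel$d == d`.
#' @param seed integer seed; the basis is fully reproducible.
#' @return an object of class `rf_basis`.
#' @examples
#' b <- build_basis(d = 3, s = 2, r = 2, kernel_spec("matern52", 0.5, 3), seed = 1)
#' b$D  # 3*2 + 3*4 = 18
#' @export
build_basis <- function(d, s, r, kernel, seed) {
  .check_kernel_spec(kernel)
  d <- as.integer(d); s <- as.integer(s); r <- as.integer(r)
  if (kernel$d != d) stop("kernel dimension does not match d")
  if (s < 1L) stop("s must be >= 1")
  if (r < 1L || r > d) stop("r must satisfy 1 <= r <= d")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  omega <- matrix(0, d, s); phase <- matrix(0, d, s)
  for (j in seq_len(d)) {
    omega[j, ] <- spectral_sample(kernel, j, s)
    phase[j, ] <- stats::runif(s, 0, 2 * pi)
  }
  blocks <- .anova_blocks(d, r)
  bsize <- vapply(blocks, function(b) s^length(b), numeric(1))
  offsets <- c(0, cumsum(bsize))
  structure(list(d = d, s = s, r = r, kernel = kernel, seed = as.integer(seed),
                 omega = omega, phase = phase, blocks = blocks,
                 block_sizes = bsize, offsets = offsets[-length(offsets)],
                 D = sum(bsize)),
            class = "rf_basis")
}

#' @export
print.rf_basis <- function(x, ...) {
  cat(sprintf("rf_basis: d = %d, s = %d per coordinate, interaction order r = %d\n",
              x$d, x$s, x$r))
  cat(sprintf("  %d blocks, feature dimension D = %d, kernel = %s\n",
              length(x$blocks), x$D, x$kernel$family))
  invisible(x)
}

## Feature matrix for coordinate j at points t (vector): length(t) x s.
## deriv = 0, 1, 2 (analytic derivatives of sqrt(2/s) cos(t w + b)).
.phi_mat <- function(basis, j, t, deriv = 0L) {
  if (deriv > 0L && !.kernel_differentiable(basis$kernel))
    .stop_nondiff(basis$kernel)
  w <- basis$omega[j, ]; b <- basis$phase[j, ]
  s <- basis$s
  arg <- outer(as.numeric(t), w) + matrix(b, length(t), s, byrow = TRUE)
  amp <- sqrt(2 / s)
  wm <- function(k) matrix(w^k, length(t), s, byrow = TRUE)
  switch(as.character(deriv),
    "0" = amp * cos(arg),
    "1" = -amp * wm(1) * sin(arg),
    "2" = -amp * wm(2) * cos(arg),
    stop("feature derivative order must be 0, 1 or 2"))
}

#' Univariate random Fourier features and their derivatives
#'
#' `phi(basis, j, t, 0)` is `sqrt(2/s) cos(t w + b)` elementwise over the `s`
#' frequency/phase pairs of coordinate `j`; `deriv = 1, 2` give the analytic
#' first and second derivatives in `t`.
#'
#' @param basis an [build_basis()] object.
#' @param j coordinate index.
#' @param t scalar (or vector) evaluation point.
#' @param deriv derivative order 0, 1 or 2.
#' @return an `s`-vector for scalar `t`, otherwise a `length(t) x s` matrix.
#' @export
phi <- function(basis, j, t, deriv = 0L) {
  stopifnot(inherits(basis, "rf_basis"))
  j <- as.integer(j)
  if (j < 1L || j > basis$d) stop("coordinate index j out of range")
  m <- .phi_mat(basis, j, t, as.integer(deriv))
  if (length(t) == 1L) drop(m) else m
}

## Per-block derivative orders for a row functional:
## channel block l (0..p) stacked with row kind kappa (0 = function
## evaluation, j>0 = d/dt_j).  Order of coordinate j is (j==l) + (j==kappa).
.orders_for <- function(d, l, kappa) {
  o <- integer(d)
  if (l > 0L) o[l] <- o[l] + 1L
  if (kappa > 0L) o[kappa] <- o[kappa] + 1L
  o
}

#' Tensor-product ANOVA feature vector
#'
#' Concatenates, over the basis blocks, Kronecker products of the univariate
#' feature vectors, applying derivatives as requested.  `deriv_spec` is an
#' integer vector of coordinates (length 0, 1 or 2; a repeated coordinate
#' means a second derivative).  A block whose tuple does not contain every
#' requested derivative coordinate contributes a zero segment.
#'
#' Kronecker ordering: each element of the earlier factor multiplies the
#' entire later factor, and the results are concatenated.
#'
#' @param basis an [build_basis()] object.
#' @param t numeric vector of length `d`.
#' @param deriv_spec integer vector of derivative coordinates (possibly empty).
#' @return numeric vector of length `basis$D`.
#' @export
anova_features <- function(basis, t, deriv_spec = integer(0)) {
  stopifnot(inherits(basis, "rf_basis"))
  d <- basis$d
  if (length(t) != d) stop("t must have length d = ", d)
  deriv_spec <- as.integer(deriv_spec)
  if (length(deriv_spec) > 2L) stop("at most two derivatives are supported")
  if (any(deriv_spec < 1L) || any(deriv_spec > d))
    stop("derivative coordinate outside 1..d")
  orders <- integer(d)
  for (j in deriv_spec) orders[j] <- orders[j] + 1L
  out <- numeric(basis$D)
  supp <- which(orders > 0L)
  for (bi in seq_along(basis$blocks)) {
    B <- basis$blocks[[bi]]
    if (!all(supp %in% B)) next
    v <- 1
    for (j in B) v <- kronecker(v, .phi_mat(basis, j, t[j], orders[j])[1, ])
    out[(basis$offsets[bi] + 1):(basis$offsets[bi] + basis$block_sizes[bi])] <- v
  }
  out
}

#' Derivative-augmented feature row
#'
#' The augmented feature vector stacks the ANOVA feature vector with its
#' first `p` coordinate derivatives:
#' `kind = 0` (function row) gives `[Psi; d_1 Psi; ...; d_p Psi]`, and
#' `kind = j` (gradient row, `1 <= j <= p`) gives the coordinate-`j`
#' derivative of that stacked vector, with second-order feature derivatives
#' computed analytically.  A fitted model is then
#' `f(t) = <augmented_row(t, kind = 0), c>` and its `j`-th partial is the dot
#' product with the `kind = j` row.
#'
#' @param basis an [build_basis()] object.
#' @param t numeric vector of length `d`.
#' @param p number of gradient channels (`0 <= p <= d`).
#' @param kind `0` for a function row or a gradient coordinate in `1..p`.
#' @return numeric vector of length `(p + 1) * basis$D`.
#' @export
augmented_row <- function(basis, t, p, kind = 0L) {
  stopifnot(inherits(basis, "rf_basis"))
  p <- as.integer(p); kind <- as.integer(kind)
  if (p < 0L || p > basis$d) stop("p must be between 0 and d")
  if (kind < 0L || (kind > 0L && kind > p))
    stop("kind must be 0 (function) or a gradient coordinate <= p")
  segs <- lapply(0:p, function(l) {
    ds <- c(if (l > 0L) l, if (kind > 0L) kind)
    anova_features(basis, t, as.integer(ds))
  })
  unlist(segs, use.names = FALSE)
}

## ---- factorized Gram engine -------------------------------------------
## Inner products of augmented rows computed blockwise through
## <a (x) b, c (x) e> = <a, c> <b, e>, never materializing s^k-dimensional
## segments.  Rows are grouped by kind; per group pair the per-coordinate
## factor matrices  F_j^{(a,b)} = Phi_j^{(a)}(t1) Phi_j^{(b)}(t2)^T  are
## cached and combined across blocks by Hadamard products.
.rf_cross_gram <- function(basis, T1, kinds1, T2, kinds2, p, symmetric = FALSE) {
  d <- basis$d
  T1 <- as.matrix(T1); T2 <- as.matrix(T2)
  kinds1 <- as.integer(kinds1); kinds2 <- as.integer(kinds2)
  if (!.kernel_differentiable(basis$kernel) &&
      (p > 0L || any(kinds1 > 0L) || any(kinds2 > 0L)))
    .stop_nondiff(basis$kernel)
  N1 <- nrow(T1); N2 <- nrow(T2)
  res <- matrix(0, N1, N2)
  for (k1 in unique(kinds1)) {
    idx1 <- which(kinds1 == k1)
    for (k2 in unique(kinds2)) {
      if (symmetric && k2 < k1) next   # fill by symmetry below
      idx2 <- which(kinds2 == k2)
      phi1 <- new.env(parent = emptyenv())
      phi2 <- new.env(parent = emptyenv())
      Fc <- new.env(parent = emptyenv())
      getphi <- function(env, j, o, T, idx) {
        key <- paste0(j, "_", o)
        if (is.null(env[[key]])) env[[key]] <- .phi_mat(basis, j, T[idx, j], o)
        env[[key]]
      }
      getF <- function(j, a, b) {
        key <- paste0(j, "_", a, "_", b)
        if (is.null(Fc[[key]]))
          Fc[[key]] <- tcrossprod(getphi(phi1, j, a, T1, idx1),
                                  getphi(phi2, j, b, T2, idx2))
        Fc[[key]]
      }
      acc <- matrix(0, length(idx1), length(idx2))
      for (l in 0:p) {
        a <- .orders_for(d, l, k1)
        b <- .orders_for(d, l, k2)
        req <- which(a > 0L | b > 0L)
        for (bi in seq_along(basis$blocks)) {
          B <- basis$blocks[[bi]]
          if (!all(req %in% B)) next
          .had_accum_cpp(acc, lapply(B, function(j) getF(j, a[j], b[j])))
        }
      }
      res[idx1, idx2] <- acc
      if (symmetric && k2 > k1) res[idx2, idx1] <- t(acc)
    }
  }
  res
}

#' Factorized Gram matrix of augmented feature rows
#'
#' Computes all pairwise inner products of augmented rows without
#' materializing the `(p+1) D`-dimensional vectors, by factorizing each
#' Kronecker block into per-coordinate inner products.  This enables the dual
#' ridge solve when the feature dimension exceeds the number of rows.
#'
#' @param basis an [build_basis()] object.
#' @param T `N x d` matrix of design points.
#' @param kinds integer vector of row kinds (`0` function, `j` gradient).
#' @param p number of gradient channels.
#' @return symmetric positive semidefinite `N x N` matrix.
#' @export
factorized_gram <- function(basis, T, kinds, p) {
  G <- .rf_cross_gram(basis, T, kinds, T, kinds, p, symmetric = TRUE)
  (G + t(G)) / 2
}

## Explicit design matrix (primal path): N x (p+1) D.  Column layout is
## channel-major, then blocks in basis order, then Kronecker order within a
## block.  Only sensible when (p+1) D is moderate.
.design_matrix <- function(basis, T, kinds, p) {
  d <- basis$d
  T <- as.matrix(T); kinds <- as.integer(kinds)
  if (!.kernel_differentiable(basis$kernel) && (p > 0L || any(kinds > 0L)))
    .stop_nondiff(basis$kernel)
  N <- nrow(T); D <- basis$D
  X <- matrix(0, N, (p + 1L) * D)
  for (k in unique(kinds)) {
    idx <- which(kinds == k)
    for (l in 0:p) {
      a <- .orders_for(d, l, k)
      supp <- which(a > 0L)
      for (bi in seq_along(basis$blocks)) {
        B <- basis$blocks[[bi]]
        if (!all(supp %in% B)) next
        M <- .phi_mat(basis, B[1], T[idx, B[1]], a[B[1]])
        for (j in B[-1]) M <- .rowwise_kron(M, .phi_mat(basis, j, T[idx, j], a[j]))
        cols <- l * D + basis$offsets[bi] + seq_len(basis$block_sizes[bi])
        X[idx, cols] <- M
      }
    }
  }
  X
}

## Evaluate <Psi-row(t, deriv), c> for many points t via sequential tensor
## contraction (never materializing s^k columns per point beyond one
## intermediate of width s^(k-1)); the per-point contraction runs in
## compiled code.  deriv = 0 evaluates the function, deriv = j its j-th
## partial derivative.  Returns a numeric vector.
.contract_predict <- function(basis, cvec, Tnew, deriv = 0L, p, chunk = 2000L) {
  d <- basis$d; s <- basis$s; D <- basis$D
  Tnew <- as.matrix(Tnew)
  if (!.kernel_differentiable(basis$kernel) && (p > 0L || deriv > 0L))
    .stop_nondiff(basis$kernel)
  M <- nrow(Tnew)
  out <- numeric(M)
  starts <- seq(1L, M, by = chunk)
  for (st in starts) {
    rows <- st:min(st + chunk - 1L, M)
    acc <- numeric(length(rows))
    pcache <- new.env(parent = emptyenv())
    getphi <- function(j, o) {     # transposed: s x nc, point = column
      key <- paste0(j, "_", o)
      if (is.null(pcache[[key]]))
        pcache[[key]] <- t(.phi_mat(basis, j, Tnew[rows, j], o))
      pcache[[key]]
    }
    for (l in 0:p) {
      a <- .orders_for(d, l, as.integer(deriv))
      supp <- which(a > 0L)
      for (bi in seq_along(basis$blocks)) {
        B <- basis$blocks[[bi]]
        if (!all(supp %in% B)) next
        cseg <- cvec[l * D + basis$offsets[bi] + seq_len(basis$block_sizes[bi])]
        k <- length(B)
        if (k == 1L) {
          acc <- acc + drop(crossprod(getphi(B[1], a[B[1]]), cseg))
        } else {
          ## stage 1 (BLAS): contract the slowest-index factor
          Cm <- matrix(cseg, nrow = s^(k - 1L), ncol = s)
          W <- Cm %*% getphi(B[1], a[B[1]])       # s^(k-1) x nc
          acc <- acc + .contract_rest_cpp(lapply(B[-1], function(j)
            getphi(j, a[j])), W)
        }
      }
    }
    out[rows] <- acc
  }
  out
}

## Coefficients from a dual solution: c = X^T gamma accumulated blockwise via
## Khatri-Rao factors, avoiding per-row (p+1)D vectors.
.dual_to_coef <- function(basis, T, kinds, p, gamma) {
  d <- basis$d; s <- basis$s; D <- basis$D
  T <- as.matrix(T); kinds <- as.integer(kinds)
  cvec <- numeric((p + 1L) * D)
  for (k in unique(kinds)) {
    idx <- which(kinds == k)
    g <- gamma[idx]
    for (l in 0:p) {
      a <- .orders_for(d, l, k)
      supp <- which(a > 0L)
      for (bi in seq_along(basis$blocks)) {
        B <- basis$blocks[[bi]]
        if (!all(supp %in% B)) next
        kk <- length(B)
        W <- .phi_mat(basis, B[1], T[idx, B[1]], a[B[1]]) * g
        if (kk == 1L) {
          seg <- colSums(W)
        } else {
          KR <- .phi_mat(basis, B[2], T[idx, B[2]], a[B[2]])
          if (kk > 2L) for (m in 3:kk)
            KR <- .rowwise_kron(KR, .phi_mat(basis, j <- B[m], T[idx, B[m]], a[B[m]]))
          seg <- as.vector(t(crossprod(W, KR)))   # s x s^(k-1), leading factor slowest
        }
        cols <- l * D + basis$offsets[bi] + seq_len(basis$block_sizes[bi])
        cvec[cols] <- cvec[cols] + seg
      }
    }
  }
  cvec
}

#' Serialize a random feature basis to JSON
#'
#' Stores frequencies, phases, block list and kernel so a fit can be replayed
#' exactly.
#'
#' @param basis an [build_basis()] object.
#' @param path file path to write.
#' @export
basis_to_json <- function(basis, path) {
  obj <- list(d = basis$d, s = basis$s, r = basis$r, seed = basis$seed,
              kernel = list(family = basis$kernel$family,
                            scales = basis$kernel$scales, d = basis$kernel$d),
              omega = basis$omega, phase = basis$phase,
              blocks = basis$blocks)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a random feature basis from JSON
#'
#' @param path file written by [basis_to_json()].
#' @return an `rf_basis` object.
#' @export
basis_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ks <- kernel_spec(obj$kernel$family, obj$kernel$scales, obj$kernel$d)
  b <- build_basis(obj$d, obj$s, obj$r, ks, obj$seed)
  b$omega <- matrix(as.numeric(obj$omega), obj$d, obj$s)
  b$phase <- matrix(as.numeric(obj$phase), obj$d, obj$s)
  b
}
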