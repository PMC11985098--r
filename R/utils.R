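## Internal helpers shared across modules.

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

## Deterministic child seeds from one master seed (kept below 2^31).
.child_seeds <- function(seed, n) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

## All strictly increasing index tuples of sizes 1..r out of 1..d,
## ordered by size then lexicographically.
.anova_blocks <- function(d, r) {
  stopifnot(r >= 1, r <= d)
  out <- list()
  for (k in seq_len(r)) {
    cmb <- utils::combn(d, k)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
  }
  out
}

## Row-wise Kronecker (Khatri-Rao) product of two matrices with equal row
## counts; column order follows the convention that each element of the
## earlier factor scales the entire later factor.
.rowwise_kron <- function(A, B) {
  sa <- ncol(A); sb <- ncol(B)
  A[, rep(seq_len(sa), each = sb), drop = FALSE] *
    B[, rep(seq_len(sb), times = sa), drop = FALSE]
}

## Affine map of designs into the unit cube given a 2 x d domain box.
.to_unit <- function(T, domain) {
  T <- as.matrix(T)
  lo <- domain[1, ]; wid <- domain[2, ] - domain[1, ]
  sweep(sweep(T, 2, lo, "-"), 2, wid, "/")
}

.box_widths <- function(domain) domain[2, ] - domain[1, ]

.default_domain <- function(d) rbind(rep(0, d), rep(1, d))

`%||%` <- function(a, b) if (is.null(a)) b else a
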