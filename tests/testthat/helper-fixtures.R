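## Shared fixture builders (everything generated in code).

fd_shift <- function(M, j, h) { M[, j] <- M[, j] + h; M }

## small smooth two-dimensional truth with a genuine interaction term
truth_2d <- function() {
  ss_truth(list(
    list(coef = 1, atoms = list(list(j = 1, fun = "sin", par = 1))),
    list(coef = 1, atoms = list(list(j = 2, fun = "cos", par = 1))),
    list(coef = 0.5, atoms = list(list(j = 1, fun = "poly", par = 2),
                                  list(j = 2, fun = "lin")))))
}

## additive truth in d coordinates (sin/cos alternating)
truth_additive <- function(d) {
  ss_truth(lapply(seq_len(d), function(j)
    list(coef = 1, atoms = list(list(j = j, fun = if (j %% 2) "sin" else "cos",
                                     par = 1)))))
}

## dataset whose responses lie exactly in the span of a given basis
in_span_data <- function(basis, p, n0 = 40, seed = 1, sd = 0.3) {
  set.seed(seed)
  d <- basis$d
  cstar <- rnorm((p + 1) * basis$D, sd = sd)
  designs <- lapply(0:p, function(jc) matrix(runif(n0 * d), n0, d))
  responses <- lapply(0:p, function(jc) {
    X <- gradspline:::.design_matrix(basis, designs[[jc + 1]],
                                     rep(jc, n0), p)
    drop(X %*% cstar)
  })
  list(data = gradient_data(designs, responses), cstar = cstar)
}
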