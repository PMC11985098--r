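#include <Rcpp.h>
using namespace Rcpp;

// Second stage of the blockwise tensor contraction used for model
// evaluation.  Stage one (done in R with BLAS) contracts the leading factor:
//   W[rest, i] = sum_{v1} c[(v1-1) s^(k-1) + rest] * phi_1[v1, i],
// leaving W with rows indexed by (v2,...,vk), v_k fastest.  This routine
// finishes the contraction for every point i:
//   out[i] = sum_{v2..vk} W[(v2..vk), i] * prod_m phi_m[v_m, i]
// with each remaining factor passed transposed (s x n) so that a point's
// features and its W slice are contiguous columns.  Per-point cost is
// s^(k-1) + ... + s, and W is streamed exactly once.
// [[Rcpp::export(name = ".contract_rest_cpp")]]
NumericVector contract_rest_cpp(List tphis, NumericMatrix W) {
  const int kr = tphis.size();          // number of remaining factors
  std::vector<NumericMatrix> ph(kr);
  for (int m = 0; m < kr; ++m) ph[m] = as<NumericMatrix>(tphis[m]);
  const int s = ph[0].nrow();
  const int n = ph[0].ncol();
  R_xlen_t wrows = 1;
  for (int m = 0; m < kr; ++m) {
    if (ph[m].nrow() != s || ph[m].ncol() != n)
      stop("factor matrices must share dimensions");
    wrows *= s;
  }
  if (W.nrow() != wrows || W.ncol() != n) stop("W has wrong dimensions");

  NumericVector out(n);
  std::vector<double> bufA(wrows / s > 0 ? wrows / s : 1),
                      bufB(wrows / s > 0 ? wrows / s : 1);
  for (int i = 0; i < n; ++i) {
    const double* src = &W(0, i);
    R_xlen_t m1 = wrows / s;            // size after first remaining contraction
    double* dst = bufA.data();
    // contract factors from the back (v_k fastest => stride-1 dots)
    for (int m = kr - 1; m >= 1; --m) {
      const double* pm = &ph[m](0, i);
      for (R_xlen_t j = 0; j < m1; ++j) {
        const double* cj = src + j * s;
        double acc = 0.0;
        for (int v = 0; v < s; ++v) acc += cj[v] * pm[v];
        dst[j] = acc;
      }
      src = dst;
      dst = (dst == bufA.data()) ? bufB.data() : bufA.data();
      m1 /= s;
    }
    const double* p0 = &ph[0](0, i);
    double acc = 0.0;
    for (int v = 0; v < s; ++v) acc += src[v] * p0[v];
    out[i] = acc;
  }
  return out;
}

// In-place accumulation  acc += mats[[1]] * mats[[2]] * ...  (elementwise),
// avoiding the temporaries of repeated R-level Hadamard products in the
// factorized Gram assembly.  `acc` is modified by reference; callers pass a
// freshly allocated local matrix.
// [[Rcpp::export(name = ".had_accum_cpp")]]
void had_accum_cpp(NumericMatrix acc, List mats) {
  const R_xlen_t n = (R_xlen_t) acc.nrow() * acc.ncol();
  const int m = mats.size();
  if (m < 1) stop("need at least one matrix");
  std::vector<const double*> ptr(m);
  for (int j = 0; j < m; ++j) {
    NumericMatrix M = as<NumericMatrix>(mats[j]);
    if ((R_xlen_t) M.nrow() * M.ncol() != n) stop("dimension mismatch");
    ptr[j] = REAL(M);
  }
  double* a = REAL(acc);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = ptr[0][i];
    for (int j = 1; j < m; ++j) v *= ptr[j][i];
    a[i] += v;
  }
}
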