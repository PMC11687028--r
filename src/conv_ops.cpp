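#include <Rcpp.h>
using namespace Rcpp;

// Patch gather for im2col 3D convolution.
// X: (n x F) batch, spatial-position-fastest layout per channel block.
// idx: (npos x P) source column in X for each (output position, patch
// element); 0 marks zero padding.
// Returns M: (n*npos x P) with row order sample-fastest, then position.
// [[Rcpp::export(name = ".im2col")]]
NumericMatrix im2col_gather(NumericMatrix X, IntegerMatrix idx) {
  const int n = X.nrow();
  const int npos = idx.nrow();
  const int P = idx.ncol();
  NumericMatrix M(n * npos, P);
  const double* xp = REAL(X);
  double* mp = REAL(M);
  for (int k = 0; k < P; ++k) {
    double* mcol = mp + (R_xlen_t)k * n * npos;
    for (int pos = 0; pos < npos; ++pos) {
      int src = idx(pos, k);
      double* dst = mcol + (R_xlen_t)pos * n;
      if (src == 0) {
        for (int i = 0; i < n; ++i) dst[i] = 0.0;
      } else {
        const double* s = xp + (R_xlen_t)(src - 1) * n;
        for (int i = 0; i < n; ++i) dst[i] = s[i];
      }
    }
  }
  return M;
}

// Adjoint of im2col_gather: scatter-add patch gradients back to the
// input layout. dM: (n*npos x P); returns dX: (n x F).
// [[Rcpp::export(name = ".col2im")]]
NumericMatrix col2im_scatter(NumericMatrix dM, IntegerMatrix idx, int Fdim) {
  const int npos = idx.nrow();
  const int P = idx.ncol();
  const int n = dM.nrow() / npos;
  NumericMatrix dX(n, Fdim);
  const double* mp = REAL(dM);
  double* xp = REAL(dX);
  for (int k = 0; k < P; ++k) {
    const double* mcol = mp + (R_xlen_t)k * n * npos;
    for (int pos = 0; pos < npos; ++pos) {
      int src = idx(pos, k);
      if (src == 0) continue;
      double* dst = xp + (R_xlen_t)(src - 1) * n;
      const double* s = mcol + (R_xlen_t)pos * n;
      for (int i = 0; i < n; ++i) dst[i] += s[i];
    }
  }
  return dX;
}
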