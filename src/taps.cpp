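#include <Rcpp.h>
using namespace Rcpp;

// Vertical 7-tap convolution support. Feature maps are (H, M) matrices
// where M = width * channels; the channel-mixing GEMM happens in R/BLAS,
// these kernels do the row-shifted tap accumulation (forward) and the
// tap expansion (backward). Tap k (0..6) carries row shift (k-3)*dil;
// rows outside the frame are zero (zero padding).

// y[i, m] = sum_k Z[i + (k-3)*dil, k*M + m]
// [[Rcpp::export]]
NumericMatrix tap_accum(const NumericMatrix& Z, int M, int dil) {
  const int H = Z.nrow();
  const int K = Z.ncol() / M;
  NumericMatrix y(H, M);
  for (int k = 0; k < K; ++k) {
    const int s = (k - (K - 1) / 2) * dil;
    const int lo = std::max(0, -s), hi = std::min(H, H - s);
    for (int m = 0; m < M; ++m) {
      const double* zc = &Z(0, k * M + m);
      double* yc = &y(0, m);
      for (int i = lo; i < hi; ++i) yc[i] += zc[i + s];
    }
  }
  return y;
}

// DT[j, k*M + m] = dy[j - (k-3)*dil, m] (zero where out of range)
// [[Rcpp::export]]
NumericMatrix tap_expand(const NumericMatrix& dy, int dil) {
  const int H = dy.nrow(), M = dy.ncol(), K = 7;
  NumericMatrix DT(H, M * K);
  for (int k = 0; k < K; ++k) {
    const int s = (k - 3) * dil;
    const int lo = std::max(0, s), hi = std::min(H, H + s);
    for (int m = 0; m < M; ++m) {
      const double* dc = &dy(0, m);
      double* tc = &DT(0, k * M + m);
      for (int j = lo; j < hi; ++j) tc[j] = dc[j - s];
    }
  }
  return DT;
}
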