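// Gather/scatter kernels for the spectral remap: each output bin draws from
// (or deposits into, for the adjoint) a fixed set of M kernel taps on the
// padded source axis. Complex data are passed as interleaved re/im vectors.

#include <Rcpp.h>
using namespace Rcpp;

// out[r] = sum_q w(r,q) * src[idx(r,q)]
// [[Rcpp::export(name = ".spec_gather_cpp")]]
ComplexVector spec_gather_cpp(ComplexVector src, IntegerMatrix idx,
                              NumericMatrix w) {
  int n = idx.nrow(), m = idx.ncol();
  ComplexVector out(n);
  for (int r = 0; r < n; ++r) {
    double re = 0, im = 0;
    for (int q = 0; q < m; ++q) {
      int j = idx(r, q);
      if (j == 0) continue;            // 0 marks an invalid row
      double ww = w(r, q);
      re += ww * src[j - 1].r;
      im += ww * src[j - 1].i;
    }
    out[r].r = re; out[r].i = im;
  }
  return out;
}

// adjoint: dst[idx(r,q)] += w(r,q) * y[r]
// [[Rcpp::export(name = ".spec_scatter_cpp")]]
ComplexVector spec_scatter_cpp(ComplexVector y, IntegerMatrix idx,
                               NumericMatrix w, int n_src) {
  int n = idx.nrow(), m = idx.ncol();
  ComplexVector out(n_src);
  for (int j = 0; j < n_src; ++j) { out[j].r = 0; out[j].i = 0; }
  for (int r = 0; r < n; ++r) {
    double yr = y[r].r, yi = y[r].i;
    if (yr == 0 && yi == 0) continue;
    for (int q = 0; q < m; ++q) {
      int j = idx(r, q);
      if (j == 0) continue;
      double ww = w(r, q);
      out[j - 1].r += ww * yr;
      out[j - 1].i += ww * yi;
    }
  }
  return out;
}
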