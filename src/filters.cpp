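#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, single channel, in place on y.
static void lfilter1(const std::vector<double>& b, const std::vector<double>& a,
                     const double* x, double* y, R_xlen_t n, std::vector<double> z) {
  const R_xlen_t nb = (R_xlen_t)b.size();
  z.resize(nb, 0.0);   // one trailing always-zero state slot
  for (R_xlen_t i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (R_xlen_t j = 1; j < nb; ++j) {
      z[j - 1] = b[j] * xi + z[j] - a[j] * yi;
    }
    y[i] = yi;
  }
}

// Zero-phase forward-backward filtering of each column of x.
// zi: steady-state unit-step initial conditions (length max(nb,na)-1),
// scaled by the first sample of the (extended) input, as in the classic
// filtfilt formulation. Columns are odd-extended by padlen samples at
// both ends before filtering and trimmed afterwards.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt(NumericVector b, NumericVector a,
                           NumericMatrix x, NumericVector zi, int padlen) {
  const R_xlen_t n = x.nrow(), nc = x.ncol();
  if (padlen < 0) stop("padlen must be >= 0");
  if ((R_xlen_t)padlen >= n)
    stop("signal length (%d) must exceed pad length (%d)", (int)n, padlen);
  const R_xlen_t m = n + 2 * (R_xlen_t)padlen;
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  // normalise so that a[0] == 1
  const double a0 = aa[0];
  for (auto& v : bb) v /= a0;
  for (auto& v : aa) v /= a0;
  size_t nfilt = std::max(bb.size(), aa.size());
  bb.resize(nfilt, 0.0); aa.resize(nfilt, 0.0);

  NumericMatrix out(n, nc);
  std::vector<double> ext(m), tmp(m);
  for (R_xlen_t c = 0; c < nc; ++c) {
    const double* col = &x(0, c);
    // odd extension: 2*x[0] - x[pad..1], x, 2*x[n-1] - x[n-2..n-1-pad]
    for (R_xlen_t i = 0; i < padlen; ++i) ext[i] = 2.0 * col[0] - col[padlen - i];
    for (R_xlen_t i = 0; i < n; ++i) ext[padlen + i] = col[i];
    for (R_xlen_t i = 0; i < padlen; ++i) ext[padlen + n + i] = 2.0 * col[n - 1] - col[n - 2 - i];
    // forward pass
    std::vector<double> z(zi.size());
    for (size_t j = 0; j < z.size(); ++j) z[j] = zi[j] * ext[0];
    lfilter1(bb, aa, ext.data(), tmp.data(), m, z);
    // reverse
    std::reverse(tmp.begin(), tmp.end());
    for (size_t j = 0; j < z.size(); ++j) z[j] = zi[j] * tmp[0];
    lfilter1(bb, aa, tmp.data(), ext.data(), m, z);
    std::reverse(ext.begin(), ext.end());
    for (R_xlen_t i = 0; i < n; ++i) out(i, c) = ext[padlen + i];
  }
  return out;
}

// Unfold a (Cin x L x B) array into a (Cin*k) x (Lout*B) matrix for
// stride-s 1-D convolution with zero padding pad_l/pad_r.
// Column ordering: for each batch element b, Lout consecutive columns.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int k, int stride, int pad_l, int pad_r) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 3) stop("x must be a 3-d array (channels x length x batch)");
  const int cin = dim[0], L = dim[1], B = dim[2];
  const int Lp = L + pad_l + pad_r;
  const int lout = (Lp - k) / stride + 1;
  if (lout < 1) stop("kernel longer than padded input");
  NumericMatrix out(cin * k, lout * B);
  const double* xd = x.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = xd + (R_xlen_t)b * cin * L;
    for (int t = 0; t < lout; ++t) {
      double* oc = &out(0, b * lout + t);
      const int start = t * stride - pad_l;
      for (int j = 0; j < k; ++j) {
        const int pos = start + j;
        double* dst = oc + (R_xlen_t)j * cin;
        if (pos < 0 || pos >= L) {
          for (int c = 0; c < cin; ++c) dst[c] = 0.0;
        } else {
          const double* src = xb + (R_xlen_t)pos * cin;
          for (int c = 0; c < cin; ++c) dst[c] = src[c];
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: fold column-matrix gradients back onto the input.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix g, IntegerVector dim, int k, int stride,
                         int pad_l, int pad_r) {
  const int cin = dim[0], L = dim[1], B = dim[2];
  const int Lp = L + pad_l + pad_r;
  const int lout = (Lp - k) / stride + 1;
  if (g.nrow() != cin * k || g.ncol() != lout * B)
    stop("gradient dimensions do not match im2col layout");
  NumericVector out((R_xlen_t)cin * L * B);
  out.attr("dim") = dim;
  double* od = out.begin();
  for (int b = 0; b < B; ++b) {
    double* ob = od + (R_xlen_t)b * cin * L;
    for (int t = 0; t < lout; ++t) {
      const double* gc = &g(0, b * lout + t);
      const int start = t * stride - pad_l;
      for (int j = 0; j < k; ++j) {
        const int pos = start + j;
        if (pos < 0 || pos >= L) continue;
        double* dst = ob + (R_xlen_t)pos * cin;
        const double* src = gc + (R_xlen_t)j * cin;
        for (int c = 0; c < cin; ++c) dst[c] += src[c];
      }
    }
  }
  return out;
}
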