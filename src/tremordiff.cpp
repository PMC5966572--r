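#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial conditions.
// b, a must be the same length with a[0] == 1 (normalised by the caller).
// zi has length(b) - 1; the updated state is attached as attribute "zf".
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int nb = b.size();
  int n = nb - 1;
  int m = x.size();
  if (a.size() != nb)
    stop("b and a must have equal length");
  if (zi.size() != n)
    stop("zi must have length(b) - 1");
  NumericVector y(m);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < m; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (n > 0 ? z[0] : 0.0);
    for (int j = 0; j < n - 1; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    if (n > 0)
      z[n - 1] = b[n] * xi - a[n] * yi;
    y[i] = yi;
  }
  y.attr("zf") = NumericVector(z.begin(), z.end());
  return y;
}

// Biased third-order cumulant C(k, l) = (1/M) * sum_n x(n) x(n+k) x(n+l)
// over all n for which the three indices are valid, for |k|, |l| <= L.
// Exploits the exact symmetry C(k, l) = C(l, k) of the triple sum.
// Returns a (2L+1) x (2L+1) matrix, row index k = -L..L, column l = -L..L.
// [[Rcpp::export]]
NumericMatrix third_order_cumulant_cpp(NumericVector x, int L) {
  int M = x.size();
  if (L >= M)
    stop("max lag L must be smaller than the segment length");
  if (L < 0)
    stop("max lag L must be nonnegative");
  NumericMatrix C(2 * L + 1, 2 * L + 1);
  const double *px = x.begin();
  std::vector<double> y(M);
  for (int k = -L; k <= L; ++k) {
    // y(n) = x(n) * x(n+k) on the k-valid range
    int klo = std::max(0, -k);
    int khi = M - 1 - std::max(0, k);
    for (int nn = klo; nn <= khi; ++nn)
      y[nn] = px[nn] * px[nn + k];
    for (int l = k; l <= L; ++l) {
      int lo = std::max(klo, -l);
      int hi = std::min(khi, M - 1 - l);
      double s = 0.0;
      for (int nn = lo; nn <= hi; ++nn)
        s += y[nn] * px[nn + l];
      s /= M;
      C(k + L, l + L) = s;
      C(l + L, k + L) = s;
    }
  }
  return C;
}
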