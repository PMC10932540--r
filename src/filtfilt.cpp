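#include <Rcpp.h>
using namespace Rcpp;

// Direct-form IIR filter of one column: y[i] = sum_j b[j] x[i-j] - sum_j a[j+1] y[i-1-j]
static void iir1(const double* b, int nb, const double* a, int na,
                 const double* x, double* y, int n) {
  int warm = std::max(nb, na);
  if (warm > n) warm = n;
  for (int i = 0; i < warm; ++i) {
    double acc = 0.0;
    int jb = std::min(nb - 1, i);
    for (int j = 0; j <= jb; ++j) acc += b[j] * x[i - j];
    int ja = std::min(na - 2, i - 1);
    for (int j = 0; j <= ja; ++j) acc -= a[j + 1] * y[i - 1 - j];
    y[i] = acc;
  }
  for (int i = warm; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < nb; ++j) acc += b[j] * x[i - j];
    for (int j = 1; j < na; ++j) acc -= a[j] * y[i - j];
    y[i] = acc;
  }
}

// Zero-phase filtering of each column of X: forward pass over the
// zero-padded signal, backward pass, truncation to the input length --
// the same algorithm as signal::filtfilt (zero initial conditions).
// [[Rcpp::export(name = ".filtfilt_mat")]]
NumericMatrix filtfilt_mat(NumericVector b, NumericVector a, NumericMatrix X) {
  int n = X.nrow(), k = X.ncol();
  int nb = b.size(), na = a.size();
  int pad = 2 * std::max(na, nb);
  int m = n + pad;
  std::vector<double> bn(nb), an(na);
  for (int j = 0; j < nb; ++j) bn[j] = b[j] / a[0];
  for (int j = 0; j < na; ++j) an[j] = a[j] / a[0];
  NumericMatrix out(n, k);
  std::vector<double> xp(m), y1(m), y2(m);
  for (int c = 0; c < k; ++c) {
    for (int i = 0; i < n; ++i) xp[i] = X(i, c);
    std::fill(xp.begin() + n, xp.end(), 0.0);
    iir1(bn.data(), nb, an.data(), na, xp.data(), y1.data(), m);
    std::reverse(y1.begin(), y1.end());
    iir1(bn.data(), nb, an.data(), na, y1.data(), y2.data(), m);
    std::reverse(y2.begin(), y2.end());
    for (int i = 0; i < n; ++i) out(i, c) = y2[i];
  }
  return out;
}
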