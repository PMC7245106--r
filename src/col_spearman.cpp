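#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Average ranks (ties share the mean rank), written into r.
static void avg_rank(const double* v, int k, std::vector<int>& ord,
                     std::vector<double>& r) {
  for (int i = 0; i < k; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  int i = 0;
  while (i < k) {
    int j = i;
    while (j + 1 < k && v[ord[j + 1]] == v[ord[i]]) ++j;
    double rk = 0.5 * (i + j) + 1.0; // mean of ranks i+1..j+1
    for (int t = i; t <= j; ++t) r[ord[t]] = rk;
    i = j + 1;
  }
}

// Spearman correlation of each column of X against y.
// Columns that are constant yield NA.
// [[Rcpp::export]]
NumericVector col_spearman_rcpp(NumericMatrix X, NumericVector y) {
  const int k = X.nrow(), n = X.ncol();
  std::vector<int> ord(k);
  std::vector<double> ry(k), rx(k);
  avg_rank(REAL(y), k, ord, ry);
  double my = 0.0;
  for (int i = 0; i < k; ++i) my += ry[i];
  my /= k;
  double sy = 0.0;
  for (int i = 0; i < k; ++i) {
    ry[i] -= my;
    sy += ry[i] * ry[i];
  }
  NumericVector out(n);
  if (sy == 0.0) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  for (int j = 0; j < n; ++j) {
    const double* col = &X(0, j);
    double lo = col[0], hi = col[0];
    for (int i = 1; i < k; ++i) {
      lo = std::min(lo, col[i]);
      hi = std::max(hi, col[i]);
    }
    if (lo == hi) {
      out[j] = NA_REAL;
      continue;
    }
    avg_rank(col, k, ord, rx);
    double mx = 0.0;
    for (int i = 0; i < k; ++i) mx += rx[i];
    mx /= k;
    double sx = 0.0, sxy = 0.0;
    for (int i = 0; i < k; ++i) {
      const double d = rx[i] - mx;
      sx += d * d;
      sxy += d * ry[i];
    }
    out[j] = sxy / std::sqrt(sx * sy);
  }
  return out;
}
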