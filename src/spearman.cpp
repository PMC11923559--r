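#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Average ranks (ties get the mean of the ranks they span), 1..n.
static void avg_ranks(const double *x, int n, std::vector<int> &ord,
                      std::vector<double> &out) {
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0; // mean of ranks i+1 .. j+1
    for (int k = i; k <= j; ++k) out[ord[k]] = r;
    i = j + 1;
  }
}

// Spearman rank correlation of each column of X with y.
// Columns with zero rank variance (constant) yield NA.
// [[Rcpp::export]]
NumericVector spearman_rho_cols(NumericMatrix X, NumericVector y) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (n < 2) stop("need at least 2 rows");
  std::vector<int> ord(n);
  std::vector<double> ry(n), rx(n);
  avg_ranks(&y[0], n, ord, ry);
  double my = 0.0;
  for (int i = 0; i < n; ++i) my += ry[i];
  my /= n;
  double syy = 0.0;
  for (int i = 0; i < n; ++i) syy += (ry[i] - my) * (ry[i] - my);
  NumericVector rho(p);
  if (syy <= 0.0) { // constant target: correlation undefined everywhere
    std::fill(rho.begin(), rho.end(), NA_REAL);
    return rho;
  }
  for (int c = 0; c < p; ++c) {
    const double *col = &X(0, c);
    avg_ranks(col, n, ord, rx);
    double mx = 0.0;
    for (int i = 0; i < n; ++i) mx += rx[i];
    mx /= n;
    double sxx = 0.0, sxy = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dx = rx[i] - mx;
      sxx += dx * dx;
      sxy += dx * (ry[i] - my);
    }
    rho[c] = (sxx > 0.0) ? sxy / std::sqrt(sxx * syy) : NA_REAL;
  }
  return rho;
}
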