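#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger mutual information (algorithm 1) for a
// scalar pair, max-norm neighbourhoods. Returns nats.

// [[Rcpp::export]]
double ksg_mi_cpp(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (k >= n) stop("k must be smaller than the sample size");
  std::vector<double> d(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j)
      d[j] = std::max(std::fabs(x[j] - x[i]), std::fabs(y[j] - y[i]));
    d[i] = R_PosInf;
    std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
    double eps = d[k - 1];  // distance to the k-th neighbour
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::fabs(x[j] - x[i]) < eps) ++nx;
      if (std::fabs(y[j] - y[i]) < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}

// Kozachenko-Leonenko nearest-neighbour differential entropy for a scalar
// series, in nats: -digamma(k) + digamma(N) + mean(log(2 * eps_i)).

// [[Rcpp::export]]
double kl_entropy_cpp(NumericVector x, int k) {
  const int n = x.size();
  if (k >= n) stop("k must be smaller than the sample size");
  std::vector<double> s(x.begin(), x.end());
  std::sort(s.begin(), s.end());
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    // k-th nearest neighbour along the sorted axis
    int lo = i - 1, hi = i + 1;
    double eps = 0.0;
    for (int m = 0; m < k; ++m) {
      double dl = lo >= 0 ? s[i] - s[lo] : R_PosInf;
      double dr = hi < n ? s[hi] - s[i] : R_PosInf;
      if (dl <= dr) { eps = dl; --lo; } else { eps = dr; ++hi; }
    }
    if (eps <= 0.0) stop("zero nearest-neighbour distance; input saturated with duplicates");
    acc += std::log(2.0 * eps);
  }
  return -R::digamma((double)k) + R::digamma((double)n) + acc / n;
}
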