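#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <cmath>
using namespace Rcpp;

// Dimensionless distance ranks: sorted ascending values receive evenly spaced
// ranks (k-1)/(n-1); ties share the mean of their would-be ranks.
static std::vector<double> unit_ranks(const NumericVector& x,
                                      std::vector<int>& o) {
  const int n = x.size();
  o.resize(n);
  std::iota(o.begin(), o.end(), 0);
  std::sort(o.begin(), o.end(), [&](int a, int b) { return x[a] < x[b]; });
  std::vector<double> r(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[o[j + 1]] == x[o[i]]) ++j;
    double mean_rank = 0.5 * (i + j);  // 0-based average position
    for (int k = i; k <= j; ++k) r[o[k]] = mean_rank / (n - 1);
    i = j + 1;
  }
  return r;
}

// Sorting-error curve of convergent cross sorting. Pairs are ordered by their
// distance rank in the conditioning space (dy); at each ranking level R the
// observed error is the mean |R_x - R_y| over pairs with R_y <= R, and the
// random-sorting expectation is the mean of R_y^2 - R_y + 1/2 over the same
// pairs (the expected |U - R_y| for U uniform on [0,1]; equals 1/3 at R = 1).

// [[Rcpp::export]]
List ccs_error_curve_cpp(NumericVector dx, NumericVector dy,
                         NumericVector levels) {
  const int n = dx.size();
  const int nl = levels.size();
  if (dy.size() != n) stop("dx and dy must have equal length");
  if (n < 2) stop("need at least two pairs");

  std::vector<int> ox, o;
  std::vector<double> rx = unit_ranks(dx, ox);
  // the dy sort order also orders the dy ranks (ties share one value)
  std::vector<double> ry = unit_ranks(dy, o);

  NumericVector obs(nl, NA_REAL), rnd(nl, NA_REAL);
  IntegerVector cnt(nl);
  double cum_err = 0.0, cum_rnd = 0.0;
  int i = 0;
  for (int l = 0; l < nl; ++l) {
    while (i < n && ry[o[i]] <= levels[l]) {
      double e = rx[o[i]] - ry[o[i]];
      cum_err += std::fabs(e);
      cum_rnd += ry[o[i]] * (ry[o[i]] - 1.0) + 0.5;
      ++i;
    }
    cnt[l] = i;
    if (i > 0) {
      obs[l] = cum_err / i;
      rnd[l] = cum_rnd / i;
    }
  }
  return List::create(_["obs"] = obs, _["rand"] = rnd, _["count"] = cnt);
}

// Precompute the conditioning-space side once for a batch of scorings that
// share dy (surrogate tests): unit ranks of dy and its sort order.

// [[Rcpp::export]]
List ccs_rank_order_cpp(NumericVector dy) {
  std::vector<int> o;
  std::vector<double> ry = unit_ranks(dy, o);
  return List::create(_["ry"] = NumericVector(ry.begin(), ry.end()),
                      _["order"] = IntegerVector(o.begin(), o.end()));
}

// Error curve against a fixed conditioning side (ry, order from
// ccs_rank_order_cpp); only dx varies across calls.

// [[Rcpp::export]]
List ccs_curve_fixed_cpp(NumericVector dx, NumericVector ry,
                         IntegerVector ord, NumericVector levels) {
  const int n = dx.size();
  const int nl = levels.size();
  if (ry.size() != n || ord.size() != n) stop("length mismatch");
  std::vector<int> ox;
  std::vector<double> rx = unit_ranks(dx, ox);
  NumericVector obs(nl, NA_REAL), rnd(nl, NA_REAL);
  IntegerVector cnt(nl);
  double cum_err = 0.0, cum_rnd = 0.0;
  int i = 0;
  for (int l = 0; l < nl; ++l) {
    while (i < n && ry[ord[i]] <= levels[l]) {
      double e = rx[ord[i]] - ry[ord[i]];
      cum_err += std::fabs(e);
      cum_rnd += ry[ord[i]] * (ry[ord[i]] - 1.0) + 0.5;
      ++i;
    }
    cnt[l] = i;
    if (i > 0) {
      obs[l] = cum_err / i;
      rnd[l] = cum_rnd / i;
    }
  }
  return List::create(_["obs"] = obs, _["rand"] = rnd, _["count"] = cnt);
}
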