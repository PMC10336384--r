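#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// type-7 quantile via partial selection (the copy is clobbered)
static double quantile7(std::vector<double>& v, double q) {
  if (v.empty()) return NA_REAL;
  double h = (v.size() - 1) * q;
  size_t lo = (size_t)std::floor(h);
  std::nth_element(v.begin(), v.begin() + lo, v.end());
  double vlo = v[lo];
  if (lo + 1 >= v.size()) return vlo;
  double vhi = *std::min_element(v.begin() + lo + 1, v.end());
  return vlo + (h - lo) * (vhi - vlo);
}

// Continuity-scaling kernel: for each reference point, grow an epsilon-ball
// in the effect-space embedding and measure the pre-image spread in the
// cause-space embedding around the matching point: the mean member distance
// (member_max = 0) or the farthest-member radius (member_max = 1). Cells
// with fewer than `min_members` neighbours are NA. Rows of `cause` and
// `effect` must refer to the same original sample times, given (0-based) in
// `times` for Theiler exclusion.
//
// The radius grid is log-spaced with upper endpoint at the `hi_q` quantile
// of the reference-to-point effect-space distances. If `eps_in` is non-empty
// it is used as the grid; otherwise the lower endpoint adapts to the data:
// the `cover_q` quantile of the references' `min_members`-th-neighbour
// distances, so a fixed fraction of references is populated at the smallest
// radius whatever the series length.

// [[Rcpp::export]]
List cs_scan_cpp(NumericMatrix cause, NumericMatrix effect,
                 IntegerVector times, IntegerVector ref,
                 NumericVector eps_in, int n_eps,
                 int theiler, int min_members, int member_max,
                 double cover_q, double hi_q) {
  const int n = cause.nrow();
  const int dc = cause.ncol(), de = effect.ncol();
  const int nr = ref.size();

  std::vector<double> d_eff((size_t)nr * n), d_cau((size_t)nr * n);
  std::vector<double> knn(nr);
  std::vector<double> all_d;
  all_d.reserve((size_t)nr * n);
  std::vector<double> scratch(n);
  for (int r = 0; r < nr; ++r) {
    const int i = ref[r];
    int nfin = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i || std::abs(times[j] - times[i]) <= theiler) {
        d_eff[(size_t)r * n + j] = R_PosInf;
        continue;
      }
      double se = 0.0, sc = 0.0;
      for (int k = 0; k < de; ++k) {
        double v = effect(j, k) - effect(i, k);
        se += v * v;
      }
      for (int k = 0; k < dc; ++k) {
        double v = cause(j, k) - cause(i, k);
        sc += v * v;
      }
      double dej = std::sqrt(se);
      d_eff[(size_t)r * n + j] = dej;
      d_cau[(size_t)r * n + j] = std::sqrt(sc);
      scratch[nfin++] = dej;
      all_d.push_back(dej);
    }
    if (nfin < min_members) { knn[r] = R_PosInf; continue; }
    std::nth_element(scratch.begin(), scratch.begin() + (min_members - 1),
                     scratch.begin() + nfin);
    knn[r] = scratch[min_members - 1];
  }

  NumericVector eps;
  if (eps_in.size() > 0) {
    eps = eps_in;
  } else {
    std::vector<double> kfin;
    for (double v : knn) if (R_finite(v)) kfin.push_back(v);
    if (kfin.empty()) stop("no reference point has enough neighbours");
    double lo = quantile7(kfin, cover_q);
    double hi = quantile7(all_d, hi_q);
    if (!(hi > 0)) stop("degenerate point cloud: all points coincide");
    if (lo <= 0) lo = hi * 1e-4;
    if (lo >= hi) lo = hi * 0.5;
    eps = NumericVector(n_eps);
    double llo = std::log(lo), lhi = std::log(hi);
    for (int e = 0; e < n_eps; ++e)
      eps[e] = std::exp(llo + (lhi - llo) * e / (n_eps - 1));
  }

  const int ne = eps.size();
  NumericMatrix delta(nr, ne);
  std::fill(delta.begin(), delta.end(), NA_REAL);
  IntegerMatrix counts(nr, ne);
  for (int r = 0; r < nr; ++r) {
    for (int e = 0; e < ne; ++e) {
      double radius = 0.0, total = 0.0;
      int m = 0;
      const double* deff = d_eff.data() + (size_t)r * n;
      const double* dcau = d_cau.data() + (size_t)r * n;
      for (int j = 0; j < n; ++j) {
        if (deff[j] <= eps[e]) {
          ++m;
          total += dcau[j];
          if (dcau[j] > radius) radius = dcau[j];
        }
      }
      counts(r, e) = m;
      if (m >= min_members) delta(r, e) = member_max ? radius : total / m;
    }
  }
  return List::create(_["delta"] = delta, _["counts"] = counts,
                      _["eps"] = eps);
}

// Batched variant for surrogate testing: the effect-space geometry (and so
// the radius grid, ball membership and reference validity) is shared across
// all candidate cause embeddings; only the cause-space distances are
// recomputed per cause. Returns the per-cause delta curve already averaged
// over the references that are valid at the smallest radius, plus the grid.

// [[Rcpp::export]]
List cs_scan_multi_cpp(List cause_list, NumericMatrix effect,
                       IntegerVector times, IntegerVector ref,
                       int n_eps, int theiler, int min_members,
                       double cover_q, double hi_q) {
  const int n = effect.nrow();
  const int de = effect.ncol();
  const int nr = ref.size();
  const int nc = cause_list.size();

  // pass 1: effect-space distances, per-reference neighbour order
  std::vector<std::vector<int>> member_order(nr);
  std::vector<std::vector<double>> member_deff(nr);
  std::vector<double> knn(nr);
  std::vector<double> all_d;
  all_d.reserve((size_t)nr * n);
  for (int r = 0; r < nr; ++r) {
    const int i = ref[r];
    std::vector<int>& ord = member_order[r];
    std::vector<double>& dv = member_deff[r];
    ord.reserve(n); dv.reserve(n);
    for (int j = 0; j < n; ++j) {
      if (j == i || std::abs(times[j] - times[i]) <= theiler) continue;
      double se = 0.0;
      for (int k = 0; k < de; ++k) {
        double v = effect(j, k) - effect(i, k);
        se += v * v;
      }
      double dej = std::sqrt(se);
      ord.push_back(j);
      dv.push_back(dej);
      all_d.push_back(dej);
    }
    std::vector<int> idx(ord.size());
    std::iota(idx.begin(), idx.end(), 0);
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return dv[a] < dv[b]; });
    std::vector<int> ord2(ord.size());
    std::vector<double> dv2(dv.size());
    for (size_t k = 0; k < idx.size(); ++k) {
      ord2[k] = ord[idx[k]];
      dv2[k] = dv[idx[k]];
    }
    ord.swap(ord2);
    dv.swap(dv2);
    knn[r] = ((int)dv.size() >= min_members) ? dv[min_members - 1] : R_PosInf;
  }

  std::vector<double> kfin;
  for (double v : knn) if (R_finite(v)) kfin.push_back(v);
  if (kfin.empty()) stop("no reference point has enough neighbours");
  double lo = quantile7(kfin, cover_q);
  double hi = quantile7(all_d, hi_q);
  if (!(hi > 0)) stop("degenerate point cloud: all points coincide");
  if (lo <= 0) lo = hi * 1e-4;
  if (lo >= hi) lo = hi * 0.5;
  NumericVector eps(n_eps);
  for (int e = 0; e < n_eps; ++e)
    eps[e] = std::exp(std::log(lo) +
                      (std::log(hi) - std::log(lo)) * e / (n_eps - 1));

  // per-reference member counts at each radius (shared across causes)
  std::vector<std::vector<int>> cut(nr, std::vector<int>(n_eps));
  std::vector<bool> valid(nr);
  int n_valid = 0;
  for (int r = 0; r < nr; ++r) {
    const std::vector<double>& dv = member_deff[r];
    for (int e = 0; e < n_eps; ++e)
      cut[r][e] = (int)(std::upper_bound(dv.begin(), dv.end(), eps[e]) -
                        dv.begin());
    valid[r] = cut[r][0] >= min_members;
    if (valid[r]) ++n_valid;
  }
  if (n_valid == 0) stop("no reference point has enough neighbours");

  // pass 2: per cause, accumulate mean member distance over valid refs
  NumericMatrix delta(nc, n_eps);
  for (int c = 0; c < nc; ++c) {
    NumericMatrix cause = cause_list[c];
    const int dcd = cause.ncol();
    std::vector<double> acc(n_eps, 0.0);
    for (int r = 0; r < nr; ++r) {
      if (!valid[r]) continue;
      const int i = ref[r];
      const std::vector<int>& ord = member_order[r];
      const int top = cut[r][n_eps - 1];
      double total = 0.0;
      int e = 0;
      // skip radii with too few members for this reference
      while (e < n_eps && cut[r][e] < min_members) ++e;
      for (int m = 0; m < top; ++m) {
        const int j = ord[m];
        double sc = 0.0;
        for (int k = 0; k < dcd; ++k) {
          double v = cause(j, k) - cause(i, k);
          sc += v * v;
        }
        total += std::sqrt(sc);
        while (e < n_eps && m + 1 == cut[r][e]) {
          acc[e] += total / cut[r][e];
          ++e;
        }
      }
      // radii whose cutoff repeats (no new members) share the value
      for (; e < n_eps; ++e)
        acc[e] += total / cut[r][e];
    }
    for (int e = 0; e < n_eps; ++e) delta(c, e) = acc[e] / n_valid;
  }
  return List::create(_["delta"] = delta, _["eps"] = eps,
                      _["n_valid"] = n_valid,
                      _["skipped_frac"] = 1.0 - (double)n_valid / nr);
}
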