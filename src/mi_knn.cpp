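#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// k-nearest-neighbour mutual information estimators (KSG family).
//
// Both estimators work on rank/neighbourhood structure only, so they are
// invariant under strictly monotone transforms of each variable.  Ties must
// be broken upstream (a tiny jitter is added by the R wrappers); the C++
// code assumes distinct values but does not require them.

// distance to the k-th nearest neighbour of point i within `d` (self
// excluded); `d` holds |x_j - x_i| for all j with d[i] = inf already set.
static double kth_smallest(std::vector<double>& d, int k) {
  std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
  return d[k - 1];
}

// KSG estimator (variant 1) for two continuous variables, Chebyshev metric
// in the joint space.  Returns MI in nats; may be slightly negative for
// (near-)independent data.
// [[Rcpp::export]]
double ksg_mi_cc(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (n != y.size()) stop("x and y must have equal length");
  if (k < 1 || k > n - 1) stop("k must be in [1, n-1]");
  double acc = 0.0;
  std::vector<double> dj(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = std::fabs(x[j] - x[i]);
      double dy = std::fabs(y[j] - y[i]);
      dj[j] = dx > dy ? dx : dy;
    }
    dj[i] = R_PosInf;
    double eps = kth_smallest(dj, k);
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::fabs(x[j] - x[i]) < eps) ++nx;
      if (std::fabs(y[j] - y[i]) < eps) ++ny;
    }
    acc += R::digamma((double)nx + 1.0) + R::digamma((double)ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}

// Continuous-discrete MI estimator (Ross 2014).  `label` holds integer
// class codes; for each point the k-th neighbour distance is measured among
// points of the same class, then neighbours within that radius are counted
// over the full sample (self included, strict inequality).
// [[Rcpp::export]]
double ksg_mi_cd(NumericVector x, IntegerVector label, int k) {
  const int n = x.size();
  if (n != label.size()) stop("x and label must have equal length");
  if (k < 1) stop("k must be >= 1");

  // class counts
  std::map<int, int> counts;
  for (int i = 0; i < n; ++i) counts[label[i]]++;
  for (auto& kv : counts)
    if (kv.second < 2) stop("every class needs at least 2 observations");

  double acc_k = 0.0, acc_lab = 0.0, acc_m = 0.0;
  std::vector<double> dsame;
  dsame.reserve(n);
  for (int i = 0; i < n; ++i) {
    const int ci = label[i];
    const int nc = counts[ci];
    const int ki = std::min(k, nc - 1);
    dsame.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i || label[j] != ci) continue;
      dsame.push_back(std::fabs(x[j] - x[i]));
    }
    std::nth_element(dsame.begin(), dsame.begin() + (ki - 1), dsame.end());
    double eps = dsame[ki - 1];
    int m = 0;
    for (int j = 0; j < n; ++j)
      if (std::fabs(x[j] - x[i]) < eps) ++m;  // includes self (distance 0)
    if (m < 1) m = 1;
    acc_k += R::digamma((double)ki);
    acc_lab += R::digamma((double)nc);
    acc_m += R::digamma((double)m);
  }
  return R::digamma((double)n) + (acc_k - acc_lab - acc_m) / n;
}
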