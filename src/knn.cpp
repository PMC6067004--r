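#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// Bounded sorted top-T list ordered by (squared distance, index); the
// lexicographic order makes ties deterministic: the smaller index wins.
struct TopList {
  int cap;
  int size;
  double* d2;
  int* idx;

  void insert(double d, int j) {
    if (size == cap && (d > d2[size - 1] ||
                        (d == d2[size - 1] && j > idx[size - 1])))
      return;
    int pos = size < cap ? size : cap - 1;
    while (pos > 0 && (d < d2[pos - 1] || (d == d2[pos - 1] && j < idx[pos - 1]))) {
      d2[pos] = d2[pos - 1];
      idx[pos] = idx[pos - 1];
      --pos;
    }
    d2[pos] = d;
    idx[pos] = j;
    if (size < cap) ++size;
  }
};

} // namespace

// Exact k-nearest-neighbour search by brute force over every unordered
// pair, O(n^2 d / 2). Returns, per point, the T nearest other points by
// Euclidean distance (ties broken toward the smaller index) plus the
// global min/max distance over all off-diagonal pairs — the anchors of
// the min-max similarity rescaling.
// [[Rcpp::export]]
List knn_brute_cpp(NumericMatrix X, int T) {
  const int n = X.nrow();
  const int d = X.ncol();
  if (n < 2) stop("need at least 2 points");
  if (T < 1 || T > n - 1) stop("T must be in [1, n-1]");

  // row-major copy and squared norms for the dot-product distance form
  std::vector<double> P(static_cast<size_t>(n) * d);
  std::vector<double> nrm(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < d; ++k) {
      const double v = X(i, k);
      P[static_cast<size_t>(i) * d + k] = v;
      s += v * v;
    }
    nrm[i] = s;
  }

  std::vector<double> top_d2(static_cast<size_t>(n) * T);
  std::vector<int> top_idx(static_cast<size_t>(n) * T);
  std::vector<TopList> top(n);
  for (int i = 0; i < n; ++i) {
    top[i].cap = T;
    top[i].size = 0;
    top[i].d2 = &top_d2[static_cast<size_t>(i) * T];
    top[i].idx = &top_idx[static_cast<size_t>(i) * T];
  }

  double d2min = R_PosInf, d2max = R_NegInf;
  for (int i = 0; i < n; ++i) {
    const double* xi = &P[static_cast<size_t>(i) * d];
    const double ni = nrm[i];
    for (int j = i + 1; j < n; ++j) {
      const double* xj = &P[static_cast<size_t>(j) * d];
      double dot = 0.0;
      for (int k = 0; k < d; ++k) dot += xi[k] * xj[k];
      double s = ni + nrm[j] - 2.0 * dot;
      if (s < 0.0) s = 0.0; // numerical guard
      top[i].insert(s, j);
      top[j].insert(s, i);
      if (s < d2min) d2min = s;
      if (s > d2max) d2max = s;
    }
    if ((i & 255) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix idx(n, T);
  NumericMatrix dst(n, T);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < T; ++t) {
      idx(i, t) = top[i].idx[t] + 1; // 1-based for R
      dst(i, t) = std::sqrt(top[i].d2[t]);
    }
  }
  return List::create(
    _["idx"] = idx,
    _["dist"] = dst,
    _["dmin"] = std::sqrt(std::max(0.0, d2min)),
    _["dmax"] = std::sqrt(std::max(0.0, d2max)));
}
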