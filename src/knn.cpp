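#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Brute-force k-nearest-neighbour search in 3D.
// Returns 1-based index matrix (N x k) and distance matrix (N x k),
// neighbours sorted by increasing distance; ties broken by smaller index.
// O(N^2 k) but with a tiny constant; adequate for desk-scale clouds (~10^5).
// [[Rcpp::export(name = ".knn_brute")]]
List knn_brute(NumericMatrix coords, int k) {
  const int n = coords.nrow();
  if (k >= n) stop("k must be smaller than the number of points");
  IntegerMatrix idx(n, k);
  NumericMatrix dst(n, k);
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
  }
  std::vector<std::pair<double, int> > cand(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      cand[j] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    cand[i].first = R_PosInf;  // exclude self
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int m = 0; m < k; ++m) {
      idx(i, m) = cand[m].second + 1;
      dst(i, m) = std::sqrt(cand[m].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// Nearest pair of points between two index sets (1-based indices in, 1-based out).
// Used to bridge disconnected kNN-graph components.
// [[Rcpp::export(name = ".nearest_between")]]
NumericVector nearest_between(NumericMatrix coords, IntegerVector a, IntegerVector b) {
  double best = R_PosInf;
  int bi = -1, bj = -1;
  for (int p = 0; p < a.size(); ++p) {
    const int i = a[p] - 1;
    for (int q = 0; q < b.size(); ++q) {
      const int j = b[q] - 1;
      const double dx = coords(i, 0) - coords(j, 0);
      const double dy = coords(i, 1) - coords(j, 1);
      const double dz = coords(i, 2) - coords(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = i; bj = j; }
    }
  }
  return NumericVector::create(bi + 1, bj + 1, std::sqrt(best));
}
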