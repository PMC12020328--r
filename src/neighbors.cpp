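#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact k-nearest-neighbor search in 2D, Euclidean distance.
// Ties in distance are broken by lower cell index so results are
// deterministic across platforms. Returns 1-based indices, n x k,
// row i sorted by (distance, index).
// [[Rcpp::export]]
IntegerMatrix knn_brute(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n_cells");
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > cand(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      cand[m++] = std::make_pair(dx * dx + dy * dy, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int q = 0; q < k; ++q) out(i, q) = cand[q].second + 1;
  }
  return out;
}

// Fixed-radius neighbors (distance <= r, excluding self), ascending index.
// [[Rcpp::export]]
List radius_brute(NumericVector x, NumericVector y, double r) {
  const int n = x.size();
  const double r2 = r * r;
  List out(n);
  std::vector<int> buf;
  for (int i = 0; i < n; ++i) {
    buf.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      if (dx * dx + dy * dy <= r2) buf.push_back(j + 1);
    }
    out[i] = IntegerVector(buf.begin(), buf.end());
  }
  return out;
}
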