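#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Minimum-cost perfect matching on a dense square cost matrix via the
// shortest-augmenting-path (Hungarian) algorithm with dual potentials,
// O(n^3). Infinite entries must be encoded as a large finite value by the
// caller. Used for the optimal-transport formulation of the q-Wasserstein
// distance between persistence diagrams (diagonal-augmented bipartite
// problem).

// [[Rcpp::export(name = ".solve_assignment_cpp")]]
List solve_assignment_cpp(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  if (n == 0) return List::create(_["cost"] = 0.0, _["match"] = IntegerVector(0));
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector match(n);
  double total = 0.0;
  for (int j = 1; j <= n; ++j) {
    match[p[j] - 1] = j; // row p[j] assigned to column j (1-based)
    total += cost(p[j] - 1, j - 1);
  }
  return List::create(_["cost"] = total, _["match"] = match);
}

// Feasibility of a perfect matching using only edges with cost <= thr
// (Kuhn's augmenting-path algorithm). Supports the binary search defining the
// bottleneck distance.

namespace {
bool try_kuhn(int i, const NumericMatrix& cost, double thr,
              std::vector<int>& matchL, std::vector<int>& matchR,
              std::vector<char>& seen) {
  int n = cost.ncol();
  for (int j = 0; j < n; ++j) {
    if (seen[j] || cost(i, j) > thr) continue;
    seen[j] = true;
    if (matchR[j] < 0 ||
        try_kuhn(matchR[j], cost, thr, matchL, matchR, seen)) {
      matchL[i] = j;
      matchR[j] = i;
      return true;
    }
  }
  return false;
}
} // namespace

// [[Rcpp::export(name = ".bottleneck_feasible_cpp")]]
bool bottleneck_feasible_cpp(NumericMatrix cost, double thr) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  std::vector<int> matchL(n, -1), matchR(n, -1);
  for (int i = 0; i < n; ++i) {
    std::vector<char> seen(n, false);
    if (!try_kuhn(i, cost, thr, matchL, matchR, seen)) return false;
  }
  return true;
}
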