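#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Standard persistence column reduction over F_p. Columns arrive in
// filtration-sorted order as concatenated (row, coef) entries; rows are
// 1-based positions in the same sorted order. Returns, per column, the pivot
// row it ends with (0 when the column reduces to zero).

// [[Rcpp::export(name = ".reduce_boundary_cpp")]]
IntegerVector reduce_boundary_cpp(int n, IntegerVector col_ptr,
                                  IntegerVector rows, IntegerVector coefs,
                                  int p) {
  // col_ptr: length n+1, 0-based offsets into rows/coefs
  std::vector<int> inv(p, 0);
  for (int a = 1; a < p; ++a)
    for (int b = 1; b < p; ++b)
      if ((a * b) % p == 1) { inv[a] = b; break; }

  std::vector<std::vector<std::pair<int, int>>> cols(n);
  for (int j = 0; j < n; ++j) {
    for (int k = col_ptr[j]; k < col_ptr[j + 1]; ++k)
      cols[j].push_back({rows[k], coefs[k]});
  }
  std::vector<int> owner(n + 1, -1); // pivot row -> column index
  std::vector<std::pair<int, int>> buf;

  for (int j = 0; j < n; ++j) {
    auto& col = cols[j];
    while (!col.empty()) {
      int low = col.back().first;
      int own = owner[low];
      if (own < 0) break;
      const auto& oc = cols[own];
      int mult = ((p - col.back().second) * (long long)inv[oc.back().second]) % p;
      // col += mult * oc (both sorted by row)
      buf.clear();
      size_t a = 0, b = 0;
      while (a < col.size() || b < oc.size()) {
        if (b == oc.size() || (a < col.size() && col[a].first < oc[b].first)) {
          buf.push_back(col[a++]);
        } else if (a == col.size() || oc[b].first < col[a].first) {
          int c = (int)(((long long)mult * oc[b].second) % p);
          if (c != 0) buf.push_back({oc[b].first, c});
          ++b;
        } else {
          int c = (int)((col[a].second + (long long)mult * oc[b].second) % p);
          if (c != 0) buf.push_back({col[a].first, c});
          ++a; ++b;
        }
      }
      col.swap(buf);
    }
    if (!col.empty()) owner[col.back().first] = j;
  }

  IntegerVector lows(n);
  for (int j = 0; j < n; ++j)
    lows[j] = cols[j].empty() ? 0 : cols[j].back().first;
  return lows;
}
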