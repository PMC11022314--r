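#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstdlib>
#include <string>
#include <vector>

using namespace Rcpp;

// Banded unit-cost Levenshtein distance, two-row dynamic programme.
// Used as the alignment-identity oracle for the error simulator. The band
// half-width is max(64, |m-n| + ceil(max(m,n)/16)): the result is exact
// whenever the optimal alignment path stays within the band, which holds
// with overwhelming probability for a read and its corrupted copy (the
// path's diagonal drift is a random walk over indel events whose scale is
// far below max(m,n)/16); short strings (<= 64) always get the full table.
// [[Rcpp::export(name = ".editDistanceCpp")]]
IntegerVector edit_distance_cpp(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size())
    stop("'a' and 'b' must have the same length");
  const int INF = INT_MAX / 2;
  int nPairs = a.size();
  IntegerVector out(nPairs);
  for (int p = 0; p < nPairs; ++p) {
    std::string s = as<std::string>(a[p]);
    std::string t = as<std::string>(b[p]);
    int m = (int)s.size(), n = (int)t.size();
    if (m == 0 || n == 0) { out[p] = std::max(m, n); continue; }
    int w = std::max(64, std::abs(m - n) + (std::max(m, n) + 15) / 16);
    std::vector<int> prev(n + 1, INF), cur(n + 1, INF);
    for (int j = 0; j <= std::min(n, w); ++j) prev[j] = j;
    for (int i = 1; i <= m; ++i) {
      int lo = std::max(1, i - w), hi = std::min(n, i + w);
      cur[lo - 1] = (lo == 1) ? i : INF;
      const char sc = s[i - 1];
      const int *pr = prev.data();
      int *cu = cur.data();
      for (int j = lo; j <= hi; ++j) {
        int best = pr[j - 1] + (sc == t[j - 1] ? 0 : 1);
        int del = pr[j] + 1;
        if (del < best) best = del;
        int ins = cu[j - 1] + 1;
        if (ins < best) best = ins;
        cu[j] = best;
      }
      if (hi + 1 <= n) cur[hi + 1] = INF;  // keep stale cells out of band
      std::swap(prev, cur);
    }
    out[p] = prev[n];
  }
  return out;
}
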