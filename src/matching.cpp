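#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact maximum-weight matching on a small general graph (n <= 22 vertices)
// by subset DP: dp[S] = best matching weight using only vertices in S; the
// lowest vertex of S is either unmatched or matched to some partner in S.
// [[Rcpp::export]]
List cpp_mwm_exact(int n, IntegerVector eu, IntegerVector ev, NumericVector ew) {
  if (n > 22) stop("exact matching limited to 22 vertices");
  int ne = (int)eu.size();
  // adjacency weight matrix; parallel edges keep the heaviest, remember id
  std::vector<double> wmat((size_t)n * n, -1.0);
  std::vector<int> emat((size_t)n * n, -1);
  for (int e = 0; e < ne; ++e) {
    int u = eu[e], v = ev[e];
    if (u == v) continue;
    size_t i1 = (size_t)u * n + v, i2 = (size_t)v * n + u;
    if (ew[e] > wmat[i1]) {
      wmat[i1] = wmat[i2] = ew[e];
      emat[i1] = emat[i2] = e;
    }
  }
  size_t NS = (size_t)1 << n;
  std::vector<double> dp(NS, 0.0);
  std::vector<int> choice(NS, -1); // partner vertex of lowest bit, -1 = skip
  for (size_t S = 1; S < NS; ++S) {
    int v = __builtin_ctzll(S);
    size_t S1 = S & ~((size_t)1 << v);
    double best = dp[S1]; int ch = -1;
    size_t rest = S1;
    while (rest) {
      int u = __builtin_ctzll(rest);
      rest &= rest - 1;
      double w = wmat[(size_t)v * n + u];
      if (w >= 0) {
        double cand = w + dp[S1 & ~((size_t)1 << u)];
        if (cand > best) { best = cand; ch = u; }
      }
    }
    dp[S] = best; choice[S] = ch;
  }
  // reconstruct
  std::vector<int> edges;
  size_t S = NS - 1;
  while (S) {
    int v = __builtin_ctzll(S);
    int u = choice[S];
    if (u < 0) { S &= ~((size_t)1 << v); continue; }
    edges.push_back(emat[(size_t)v * n + u] + 1); // 1-based edge index
    S &= ~((size_t)1 << v);
    S &= ~((size_t)1 << u);
  }
  std::sort(edges.begin(), edges.end());
  return List::create(_["weight"] = dp[NS - 1], _["edges"] = wrap(edges));
}

// Difference-array physical coverage: counts fragments covering each base.
// [[Rcpp::export]]
IntegerVector cpp_phys_cov(int len, IntegerVector starts, IntegerVector ends) {
  std::vector<int> d(len + 1, 0);
  for (int i = 0; i < starts.size(); ++i) {
    int s = std::max(0, starts[i]);
    int e = std::min(len, (int)ends[i]);
    if (e > s) { d[s] += 1; d[e] -= 1; }
  }
  IntegerVector out(len);
  int acc = 0;
  for (int i = 0; i < len; ++i) { acc += d[i]; out[i] = acc; }
  return out;
}
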