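#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Exact unit-cost edit distance, full DP with rolling rows (no band).
// [[Rcpp::export]]
int cpp_edit_dist(std::string a, std::string b) {
  int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int c = (a[i-1] == b[j-1]) ? 0 : 1;
      cur[j] = std::min({prev[j-1] + c, prev[j] + 1, cur[j-1] + 1});
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Banded global alignment with traceback. The band is widened to at least
// |n - m| + 1 so the corner is always reachable; a path leaving the band is
// scored conservatively (distance may be overestimated for band too small).
// Returns distance, the per-column operation string over {=,X,I,D}
// (I consumes query only, D target only), match count and column count.
// [[Rcpp::export]]
List cpp_edit_align(std::string a, std::string b, int band) {
  int n = (int)a.size(), m = (int)b.size();
  const int INF = INT_MAX / 4;
  int lo = std::min(0, m - n) - band;     // diagonal d = j - i range
  int hi = std::max(0, m - n) + band;
  int W = hi - lo + 1;
  std::vector<int> prev(W, INF), cur(W, INF);
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 255); // 0 diag, 1 up(I), 2 left(D)
  auto TB = [&](int i, int c) -> uint8_t& { return tb[(size_t)i * W + c]; };
  // row 0: D[0][j] = j for j in band
  for (int j = 0; j <= m; ++j) {
    int c = j - 0 - lo;
    if (c < 0 || c >= W) continue;
    prev[c] = j;
    if (j > 0) TB(0, c) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int jmin = std::max(0, i + lo), jmax = std::min(m, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      int c = j - i - lo;
      int best = INF; uint8_t op = 255;
      if (j > 0) {
        int d = prev[c] == INF ? INF
          : prev[c] + ((a[i-1] == b[j-1]) ? 0 : 1);   // diag: prev row, c same
        if (d < best) { best = d; op = 0; }
      }
      if (c + 1 < W && prev[c+1] != INF && prev[c+1] + 1 < best) {
        best = prev[c+1] + 1; op = 1;                 // up: consume query (I)
      }
      if (c - 1 >= 0 && cur[c-1] != INF && cur[c-1] + 1 < best) {
        best = cur[c-1] + 1; op = 2;                  // left: consume target (D)
      }
      if (j == 0) { best = i; op = 1; }
      cur[c] = best; TB(i, c) = op;
    }
    std::swap(prev, cur);
  }
  int cend = m - n - lo;
  if (cend < 0 || cend >= W || prev[cend] >= INF)
    return List::create(_["dist"] = NA_INTEGER);
  int dist = prev[cend];
  // traceback
  std::string ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int c = j - i - lo;
    uint8_t op = TB(i, c);
    if (op == 0) { ops.push_back(a[i-1] == b[j-1] ? '=' : 'X'); --i; --j; }
    else if (op == 1) { ops.push_back('I'); --i; }
    else if (op == 2) { ops.push_back('D'); --j; }
    else break;
  }
  std::reverse(ops.begin(), ops.end());
  int nmatch = 0;
  for (char c2 : ops) if (c2 == '=') ++nmatch;
  int ncols = (int)ops.size();
  return List::create(_["dist"] = dist, _["ops"] = ops,
                      _["nmatch"] = nmatch, _["ncols"] = ncols,
                      _["identity"] = ncols ? (double)nmatch / ncols : 0.0);
}

// Cut a global alignment (ops over {=,X,I,D}) at target window boundaries of
// size wsize. Per window: the aligned query interval [qstart, qend) and the
// match/column counts of the window's alignment slice.
// [[Rcpp::export]]
DataFrame cpp_align_windows(std::string ops, int wsize, int tlen) {
  int nw = (tlen + wsize - 1) / wsize;
  if (nw == 0) nw = 1;
  std::vector<int> qstart(nw, -1), qend(nw, -1), nmatch(nw, 0), ncols(nw, 0);
  int qi = 0, ti = 0;
  for (char op : ops) {
    int win = std::min(ti, tlen - 1) / wsize;
    if (win >= nw) win = nw - 1;
    if (qstart[win] < 0) qstart[win] = qi;
    ncols[win] += 1;
    if (op == '=') { ++nmatch[win]; ++qi; ++ti; }
    else if (op == 'X') { ++qi; ++ti; }
    else if (op == 'I') { ++qi; }
    else { ++ti; }
    qend[win] = qi;
  }
  IntegerVector w_(nw), qs(nw), qe(nw), nm(nw), nc(nw);
  NumericVector id(nw);
  for (int i = 0; i < nw; ++i) {
    w_[i] = i + 1; qs[i] = std::max(qstart[i], 0); qe[i] = std::max(qend[i], 0);
    nm[i] = nmatch[i]; nc[i] = ncols[i];
    id[i] = ncols[i] ? (double)nmatch[i] / ncols[i] : 0.0;
  }
  return DataFrame::create(_["win"] = w_, _["qstart"] = qs, _["qend"] = qe,
                           _["nmatch"] = nm, _["ncols"] = nc,
                           _["identity"] = id);
}

// Semi-global alignment: the query aligns end-to-end, target start/end free.
// Full DP, rolling rows; tracks the target start of the optimal path and the
// match/column counts for identity. Deterministic tie-break: diag > up > left,
// then smaller target end.
// [[Rcpp::export]]
List cpp_infix_align(std::string a, std::string b) {
  int n = (int)a.size(), m = (int)b.size();
  const int INF = INT_MAX / 4;
  std::vector<int> pD(m+1), cD(m+1), pS(m+1), cS(m+1), pM(m+1), cM(m+1),
                   pC(m+1), cC(m+1);
  for (int j = 0; j <= m; ++j) { pD[j] = 0; pS[j] = j; pM[j] = 0; pC[j] = 0; }
  for (int i = 1; i <= n; ++i) {
    cD[0] = i; cS[0] = 0; cM[0] = 0; cC[0] = i;
    for (int j = 1; j <= m; ++j) {
      int match = (a[i-1] == b[j-1]) ? 1 : 0;
      int dd = pD[j-1] + 1 - match;      // diag
      int du = pD[j] + 1;                // consume query
      int dl = cD[j-1] + 1;              // consume target
      if (dd <= du && dd <= dl) {
        cD[j] = dd; cS[j] = pS[j-1]; cM[j] = pM[j-1] + match; cC[j] = pC[j-1] + 1;
      } else if (du <= dl) {
        cD[j] = du; cS[j] = pS[j]; cM[j] = pM[j]; cC[j] = pC[j] + 1;
      } else {
        cD[j] = dl; cS[j] = cS[j-1]; cM[j] = cM[j-1]; cC[j] = cC[j-1] + 1;
      }
    }
    std::swap(pD, cD); std::swap(pS, cS); std::swap(pM, cM); std::swap(pC, cC);
  }
  int best = INF, bj = 0;
  for (int j = 0; j <= m; ++j) if (pD[j] < best) { best = pD[j]; bj = j; }
  double id = pC[bj] ? (double)pM[bj] / pC[bj] : 0.0;
  return List::create(_["dist"] = best, _["tstart"] = pS[bj], _["tend"] = bj,
                      _["nmatch"] = pM[bj], _["ncols"] = pC[bj],
                      _["identity"] = id);
}

// Distance-only banded edit distance: O(n*band) time, O(band) memory.
// Band auto-widened to at least |n - m| + 1; a true distance above the band
// is reported as attained at the band edge (lower bound), so callers should
// size the band generously.
// [[Rcpp::export]]
double cpp_edit_dist_banded(std::string a, std::string b, int band) {
  int n = (int)a.size(), m = (int)b.size();
  const int INF = INT_MAX / 4;
  int lo = std::min(0, m - n) - band;
  int hi = std::max(0, m - n) + band;
  int W = hi - lo + 1;
  std::vector<int> prev(W, INF), cur(W, INF);
  for (int j = 0; j <= m; ++j) {
    int c = j - lo;
    if (c >= 0 && c < W) prev[c] = j;
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int jmin = std::max(0, i + lo), jmax = std::min(m, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      int c = j - i - lo;
      int best = INF;
      if (j > 0 && prev[c] < INF) {
        best = prev[c] + ((a[i-1] == b[j-1]) ? 0 : 1);
      }
      if (c + 1 < W && prev[c+1] + 1 < best) best = prev[c+1] + 1;
      if (c - 1 >= 0 && cur[c-1] + 1 < best) best = cur[c-1] + 1;
      if (j == 0) best = i;
      cur[c] = best;
    }
    std::swap(prev, cur);
  }
  int cend = m - n - lo;
  if (cend < 0 || cend >= W || prev[cend] >= INF) return NA_REAL;
  return (double)prev[cend];
}
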