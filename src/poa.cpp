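#include <Rcpp.h>
#include <string>
#include <vector>
#include <map>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Partial-order alignment consensus. The first sequence seeds the graph as a
// chain; each subsequent sequence is globally aligned to the graph (DP over a
// topological order) and merged, matches adding support to existing nodes and
// mismatches/insertions adding branch nodes. The consensus is the heaviest
// path by traversed-edge weight.

namespace {

struct PoaGraph {
  std::vector<char> base;
  std::vector<int> support;                    // reads passing through node
  std::vector<std::vector<int>> inn, out;      // adjacency (node ids)
  std::map<std::pair<int,int>, int> ew;        // edge weights

  int add_node(char b) {
    base.push_back(b); support.push_back(0);
    inn.push_back({}); out.push_back({});
    return (int)base.size() - 1;
  }
  void add_edge(int u, int v) {
    auto key = std::make_pair(u, v);
    auto it = ew.find(key);
    if (it == ew.end()) {
      ew[key] = 1;
      out[u].push_back(v);
      inn[v].push_back(u);
    } else {
      it->second += 1;
    }
  }
  std::vector<int> topo() const {
    int n = (int)base.size();
    std::vector<int> indeg(n, 0), order;
    for (int v = 0; v < n; ++v) indeg[v] = (int)inn[v].size();
    std::vector<int> stack;
    for (int v = n - 1; v >= 0; --v) if (indeg[v] == 0) stack.push_back(v);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      order.push_back(v);
      for (int u : out[v]) if (--indeg[u] == 0) stack.push_back(u);
    }
    return order;
  }
};

const int NEG = INT_MIN / 4;

void align_and_merge(PoaGraph& g, const std::string& q,
                     int match, int mismatch, int gap) {
  int m = (int)q.size();
  if (m == 0) return;
  std::vector<int> order = g.topo();
  int n = (int)order.size();
  std::vector<int> rank(g.base.size(), -1);
  for (int i = 0; i < n; ++i) rank[order[i]] = i;
  // DP rows: 0 = virtual source, 1..n = nodes in topo order
  std::vector<std::vector<int>> S(n + 1, std::vector<int>(m + 1, NEG));
  std::vector<std::vector<uint8_t>> OP(n + 1, std::vector<uint8_t>(m + 1, 255));
  std::vector<std::vector<int>> PR(n + 1, std::vector<int>(m + 1, -1));
  for (int j = 0; j <= m; ++j) { S[0][j] = j * gap; OP[0][j] = 1; } // leading ins
  OP[0][0] = 255;
  for (int i = 1; i <= n; ++i) {
    int v = order[i - 1];
    std::vector<int> preds;
    for (int u : g.inn[v]) preds.push_back(rank[u] + 1);
    if (preds.empty()) preds.push_back(0);
    for (int j = 0; j <= m; ++j) {
      int best = NEG; uint8_t op = 255; int pr = -1;
      for (int p : preds) {
        if (j > 0 && S[p][j-1] > NEG) {   // align node base with q[j-1]
          int sc = S[p][j-1] + (g.base[v] == q[j-1] ? match : mismatch);
          if (sc > best) { best = sc; op = 0; pr = p; }
        }
        if (S[p][j] > NEG) {              // skip node (deletion)
          int sc = S[p][j] + gap;
          if (sc > best) { best = sc; op = 2; pr = p; }
        }
      }
      if (j > 0 && S[i][j-1] > NEG) {     // consume query (insertion)
        int sc = S[i][j-1] + gap;
        if (sc > best) { best = sc; op = 1; pr = i; }
      }
      S[i][j] = best; OP[i][j] = op; PR[i][j] = pr;
    }
  }
  // end state: best over sink nodes (no out-edges) at column m
  int bi = 0, bscore = S[0][m];
  for (int i = 1; i <= n; ++i) {
    int v = order[i - 1];
    if (!g.out[v].empty()) continue;
    if (S[i][m] > bscore) { bscore = S[i][m]; bi = i; }
  }
  // traceback collecting (node_or_new, qchar) in reverse
  struct Step { int node; int qpos; uint8_t op; };
  std::vector<Step> steps;
  int ci = bi, cj = m;
  while (ci != 0 || cj != 0) {
    uint8_t op = OP[ci][cj];
    if (op == 255) break;
    int v = ci > 0 ? order[ci - 1] : -1;
    if (op == 0) { steps.push_back({v, cj - 1, 0}); ci = PR[ci][cj]; --cj; }
    else if (op == 1) { steps.push_back({-1, cj - 1, 1}); --cj; }
    else { ci = PR[ci][cj]; }
  }
  std::reverse(steps.begin(), steps.end());
  // merge: walk steps, creating nodes for mismatches/insertions
  int prev = -1;
  for (const Step& st : steps) {
    int node;
    if (st.op == 0 && g.base[st.node] == q[st.qpos]) {
      node = st.node;
    } else {
      node = g.add_node(q[st.qpos]);
    }
    g.support[node] += 1;
    if (prev >= 0 && prev != node) g.add_edge(prev, node);
    prev = node;
  }
}

} // namespace

// [[Rcpp::export]]
std::string cpp_poa_consensus(CharacterVector seqs, int match, int mismatch,
                              int gap) {
  int ns = (int)seqs.size();
  if (ns == 0) return "";
  PoaGraph g;
  std::string s0 = as<std::string>(seqs[0]);
  int prev = -1;
  for (char c : s0) {
    int v = g.add_node(c);
    g.support[v] += 1;
    if (prev >= 0) g.add_edge(prev, v);
    prev = v;
  }
  for (int i = 1; i < ns; ++i)
    align_and_merge(g, as<std::string>(seqs[i]), match, mismatch, gap);
  if (ns == 1) return s0;
  // heaviest path by summed edge weight (node support only breaks ties):
  // scoring nodes themselves would let long low-support detours outweigh a
  // heavy direct edge
  std::vector<int> order = g.topo();
  int n = (int)order.size();
  std::vector<long> score(g.base.size(), 0);
  std::vector<int> from(g.base.size(), -1);
  long best = -1; int bestv = -1;
  for (int i = 0; i < n; ++i) {
    int v = order[i];
    long binc = -1; int bu = -1;
    for (int u : g.inn[v]) {
      long cand = score[u] + g.ew[{u, v}];
      if (cand > binc || (cand == binc && bu >= 0 &&
                          g.support[u] > g.support[bu])) {
        binc = cand; bu = u;
      }
    }
    score[v] = binc < 0 ? 0 : binc;
    from[v] = bu;
    if (score[v] > best ||
        (score[v] == best && bestv >= 0 &&
         g.support[v] > g.support[bestv])) {
      best = score[v]; bestv = v;
    }
  }
  std::string cons;
  for (int v = bestv; v >= 0; v = from[v]) cons.push_back(g.base[v]);
  std::reverse(cons.begin(), cons.end());
  return cons;
}
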