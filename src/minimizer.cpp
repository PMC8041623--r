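#include <Rcpp.h>
#include <string>
#include <vector>
#include <map>
#include <unordered_map>
#include <deque>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// ---- minimizer extraction -------------------------------------------------

static const uint64_t MASK53 = (1ULL << 53) - 1;

// invertible 64-bit mixer (splitmix64 finalizer): deterministic, seedless
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct Mini {
  uint64_t hash;
  int pos;      // 0-based k-mer start (in the coordinate space of the input)
  uint8_t strand; // 0 = canonical is forward
};

// Canonical (w,k)-minimizers. Windows of w consecutive k-mers; per window the
// minimum-hash k-mer is kept; k-mers containing non-ACGT are skipped.
static void extract_minimizers_span(const char* s, int n, int w, int k,
                                    std::vector<Mini>& out) {
  if (n < k) return;
  int nk = n - k + 1;
  std::vector<uint64_t> hashes(nk, UINT64_MAX);
  std::vector<uint8_t> strands(nk, 0);
  uint64_t mask = (k == 32) ? UINT64_MAX : ((1ULL << (2 * k)) - 1);
  uint64_t kf = 0, kr = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; kf = 0; kr = 0; continue; }
    kf = ((kf << 2) | (uint64_t)c) & mask;
    kr = (kr >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++run >= k) {
      int pos = i - k + 1;
      uint64_t canon = kf <= kr ? kf : kr;
      hashes[pos] = mix64(canon) & MASK53;
      strands[pos] = (kf <= kr) ? 0 : 1;
    }
  }
  int win = std::min(w, nk);
  // monotone deque of positions with valid (non-UINT64_MAX) hashes
  std::deque<int> dq;
  int last_sel = -1;
  for (int i = 0; i < nk; ++i) {
    if (hashes[i] != UINT64_MAX) {
      while (!dq.empty() && hashes[dq.back()] > hashes[i]) dq.pop_back();
      dq.push_back(i);
    }
    while (!dq.empty() && dq.front() <= i - win) dq.pop_front();
    if (i >= win - 1 && !dq.empty()) {
      int sel = dq.front();
      if (sel != last_sel) {
        out.push_back({hashes[sel], sel, strands[sel]});
        last_sel = sel;
      }
    }
  }
}

static inline void extract_minimizers_core(const std::string& s, int w, int k,
                                           std::vector<Mini>& out) {
  extract_minimizers_span(s.data(), (int)s.size(), w, k, out);
}

// [[Rcpp::export]]
DataFrame cpp_minimizers(std::string seq, int w, int k) {
  std::vector<Mini> v;
  extract_minimizers_core(seq, w, k, v);
  int n = (int)v.size();
  NumericVector h(n); IntegerVector p(n); IntegerVector s(n);
  for (int i = 0; i < n; ++i) {
    h[i] = (double)v[i].hash; p[i] = v[i].pos; s[i] = v[i].strand;
  }
  return DataFrame::create(_["hash"] = h, _["pos"] = p, _["strand"] = s);
}

// ---- index ----------------------------------------------------------------

struct MinIndex {
  int w = 0, k = 0, max_occ = 0;
  bool hpc = false;
  std::vector<std::string> ids;
  std::vector<int> lens;                  // original lengths
  std::vector<std::vector<int>> hp_maps;  // compressed->original (hpc only)
  std::vector<int> clens;                 // compressed lengths (hpc only)
  // hash -> packed hits: (target << 34) | (pos << 2) | strand
  std::unordered_map<uint64_t, std::vector<uint64_t>> table;
};

static std::string compress_hp_str(const std::string& s, std::vector<int>& map) {
  std::string c; c.reserve(s.size()); map.clear();
  size_t i = 0;
  while (i < s.size()) {
    c.push_back(s[i]); map.push_back((int)i);
    size_t j = i;
    while (j < s.size() && s[j] == s[i]) ++j;
    i = j;
  }
  return c;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector ids, CharacterVector seqs, int w, int k,
                     bool hpc, int max_occ) {
  MinIndex* idx = new MinIndex();
  idx->w = w; idx->k = k; idx->hpc = hpc; idx->max_occ = max_occ;
  int nt = (int)ids.size();
  for (int t = 0; t < nt; ++t) {
    std::string id = as<std::string>(ids[t]);
    std::string s = as<std::string>(seqs[t]);
    idx->ids.push_back(id);
    idx->lens.push_back((int)s.size());
    std::vector<Mini> mins;
    if (hpc) {
      std::vector<int> map;
      std::string c = compress_hp_str(s, map);
      idx->clens.push_back((int)c.size());
      idx->hp_maps.push_back(std::move(map));
      extract_minimizers_core(c, w, k, mins);
    } else {
      extract_minimizers_core(s, w, k, mins);
    }
    for (const Mini& m : mins) {
      idx->table[m.hash].push_back(((uint64_t)t << 34) |
                                   ((uint64_t)m.pos << 2) | m.strand);
    }
  }
  XPtr<MinIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP idxp) {
  XPtr<MinIndex> idx(idxp);
  IntegerVector occ;
  std::vector<int> counts;
  for (auto& kv : idx->table) counts.push_back((int)kv.second.size());
  std::sort(counts.begin(), counts.end());
  return List::create(_["w"] = idx->w, _["k"] = idx->k, _["hpc"] = idx->hpc,
                      _["max_occ"] = idx->max_occ,
                      _["n_targets"] = (int)idx->ids.size(),
                      _["target_ids"] = wrap(idx->ids),
                      _["target_lens"] = wrap(idx->lens),
                      _["n_distinct_minimizers"] = (int)idx->table.size(),
                      _["occ_counts"] = wrap(counts));
}

// ---- chaining -------------------------------------------------------------

// Longest strictly increasing subsequence over tpos, anchors sorted by
// (qpos asc, tpos desc) so qpos is strictly increasing along any chain.
// Returns chain member indices (into the sorted order).
static int lis_chain(std::vector<std::pair<int,int>>& a /* (q,t) */,
                     std::vector<int>* members) {
  std::sort(a.begin(), a.end(), [](const std::pair<int,int>& x,
                                   const std::pair<int,int>& y) {
    if (x.first != y.first) return x.first < y.first;
    return x.second > y.second;
  });
  int n = (int)a.size();
  if (n == 0) return 0;
  std::vector<int> tails;      // indices into a: smallest tail t for length L
  std::vector<int> prev(n, -1), lenat(n, 0);
  for (int i = 0; i < n; ++i) {
    int t = a[i].second;
    int lo = 0, hi = (int)tails.size();
    while (lo < hi) {          // first tail with t >= current t
      int mid = (lo + hi) / 2;
      if (a[tails[mid]].second < t) lo = mid + 1; else hi = mid;
    }
    if (lo == (int)tails.size()) tails.push_back(i); else tails[lo] = i;
    prev[i] = lo > 0 ? tails[lo - 1] : -1;
    lenat[i] = lo + 1;
  }
  int best = tails.back();
  int L = (int)tails.size();
  if (members) {
    members->clear();
    for (int cur = best; cur >= 0; cur = prev[cur]) members->push_back(cur);
    std::reverse(members->begin(), members->end());
  }
  return L;
}

// [[Rcpp::export]]
int cpp_chain_score(IntegerVector qpos, IntegerVector tpos) {
  std::vector<std::pair<int,int>> a(qpos.size());
  for (int i = 0; i < qpos.size(); ++i) a[i] = {qpos[i], tpos[i]};
  return lis_chain(a, nullptr);
}

struct MapResult {
  int target = -1;   // 0-based; -1 unmapped
  int pos = 0;       // 0-based start on target, original coordinates
  int strand = 0;    // 0 = '+', 1 = '-'
  int mapq = 0;
  double covered = 0.0;
  int n_anchors = 0;
  int score = 0, second = 0;
};

struct Anchor { uint64_t key; int q; int t; };

// map a query span; thread_local-free, caller supplies scratch buffers
static MapResult map_one_span(const char* qs, int qn, const MinIndex& idx,
                              std::vector<Mini>& mins,
                              std::vector<Anchor>& anchors) {
  MapResult res;
  int qlen = qn;
  if (qlen < idx.k) return res;
  mins.clear();
  extract_minimizers_span(qs, qn, idx.w, idx.k, mins);
  if (mins.empty()) return res;
  anchors.clear();
  for (const Mini& m : mins) {
    auto it = idx.table.find(m.hash);
    if (it == idx.table.end()) continue;
    const std::vector<uint64_t>& hits = it->second;
    if (idx.max_occ > 0 && (int)hits.size() > idx.max_occ) continue;
    for (uint64_t h : hits) {
      int t = (int)(h >> 34);
      int tpos = (int)((h >> 2) & ((1ULL << 32) - 1));
      int tstrand = (int)(h & 1);
      int rel = (m.strand == tstrand) ? 0 : 1;
      anchors.push_back({((uint64_t)t << 1) | rel, m.pos,
                         rel == 0 ? tpos : -tpos});
    }
  }
  if (anchors.empty()) return res;
  std::sort(anchors.begin(), anchors.end(),
            [](const Anchor& a, const Anchor& b) {
              if (a.key != b.key) return a.key < b.key;
              if (a.q != b.q) return a.q < b.q;
              return a.t > b.t;
            });
  int s1 = 0, s2 = 0;
  uint64_t bestkey = 0;
  std::vector<int> bestmem;
  size_t best_lo = 0, best_hi = 0;
  std::vector<std::pair<int,int>> grp;
  std::vector<int> mem;
  size_t i = 0, n = anchors.size();
  while (i < n) {
    size_t j = i;
    while (j < n && anchors[j].key == anchors[i].key) ++j;
    grp.clear();
    for (size_t t2 = i; t2 < j; ++t2) grp.push_back({anchors[t2].q, anchors[t2].t});
    int sc = lis_chain(grp, &mem);
    if (sc > s1) {
      s2 = s1; s1 = sc; bestkey = anchors[i].key;
      bestmem = mem; best_lo = i; best_hi = j;
    } else if (sc > s2) {
      s2 = sc;
    }
    i = j;
  }
  if (s1 == 0) return res;
  // secondary chain within the winning group (tandem / multi-copy targets):
  // re-chain the group without the primary chain's anchors
  if ((int)(best_hi - best_lo) > s1) {
    grp.clear();
    for (size_t t2 = best_lo; t2 < best_hi; ++t2)
      grp.push_back({anchors[t2].q, anchors[t2].t});
    std::sort(grp.begin(), grp.end(), [](const std::pair<int,int>& x,
                                         const std::pair<int,int>& y) {
      if (x.first != y.first) return x.first < y.first;
      return x.second > y.second;
    });
    std::vector<bool> inchain(grp.size(), false);
    for (int m2 : bestmem) inchain[m2] = true;
    std::vector<std::pair<int,int>> rest;
    for (size_t t2 = 0; t2 < grp.size(); ++t2)
      if (!inchain[t2]) rest.push_back(grp[t2]);
    if (!rest.empty()) {
      int sc2 = lis_chain(rest, nullptr);
      if (sc2 > s2) s2 = sc2;
    }
  }
  int target = (int)(bestkey >> 1);
  int rel = (int)(bestkey & 1);
  // rebuild the winning group's sorted anchor list to project coordinates
  grp.clear();
  for (size_t t2 = best_lo; t2 < best_hi; ++t2)
    grp.push_back({anchors[t2].q, anchors[t2].t});
  std::sort(grp.begin(), grp.end(), [](const std::pair<int,int>& x,
                                       const std::pair<int,int>& y) {
    if (x.first != y.first) return x.first < y.first;
    return x.second > y.second;
  });
  int qfirst = grp[bestmem.front()].first;
  int qlast = grp[bestmem.back()].first;
  int tfirst = grp[bestmem.front()].second;
  int tlast = grp[bestmem.back()].second;
  long covered = qlast + idx.k - qfirst;
  int pos_c;
  int tlen_c = idx.hpc ? idx.clens[target] : idx.lens[target];
  if (rel == 0) {
    pos_c = tfirst - qfirst;
  } else {
    int tmin = -tlast;
    pos_c = tmin - (qlen - (qlast + idx.k));
  }
  if (pos_c < 0) pos_c = 0;
  if (pos_c > tlen_c - 1) pos_c = tlen_c - 1;
  int pos = pos_c;
  if (idx.hpc) pos = idx.hp_maps[target][pos_c];
  res.target = target;
  res.pos = pos;
  res.strand = rel;
  res.mapq = std::min(60, (int)std::lround(60.0 * (1.0 - (double)s2 / s1)));
  res.covered = (double)covered / qlen;
  res.n_anchors = s1;
  res.score = s1;
  res.second = s2;
  return res;
}

static MapResult map_one(const std::string& seq, const MinIndex& idx) {
  std::vector<Mini> mins;
  std::vector<Anchor> anchors;
  if (idx.hpc) {
    std::vector<int> qmap;
    std::string cseq = compress_hp_str(seq, qmap);
    return map_one_span(cseq.data(), (int)cseq.size(), idx, mins, anchors);
  }
  return map_one_span(seq.data(), (int)seq.size(), idx, mins, anchors);
}

// [[Rcpp::export]]
DataFrame cpp_map_batch(CharacterVector seqs, SEXP idxp) {
  XPtr<MinIndex> idx(idxp);
  int n = (int)seqs.size();
  IntegerVector target(n), pos(n), strand(n), mapq(n), nanch(n), score(n), second(n);
  NumericVector covered(n);
  for (int i = 0; i < n; ++i) {
    MapResult r = map_one(as<std::string>(seqs[i]), *idx);
    if (r.target < 0) {
      target[i] = NA_INTEGER; pos[i] = NA_INTEGER; strand[i] = NA_INTEGER;
      mapq[i] = 0; covered[i] = 0.0; nanch[i] = 0; score[i] = 0; second[i] = 0;
    } else {
      target[i] = r.target + 1; pos[i] = r.pos; strand[i] = r.strand;
      mapq[i] = r.mapq; covered[i] = r.covered; nanch[i] = r.n_anchors;
      score[i] = r.score; second[i] = r.second;
    }
  }
  return DataFrame::create(_["target"] = target, _["pos"] = pos,
                           _["strand"] = strand, _["mapq"] = mapq,
                           _["covered"] = covered, _["n_anchors"] = nanch,
                           _["score"] = score, _["second"] = second);
}

// All co-linear chains (one per target/strand group) for each query, for
// layout-style uses where secondary hits matter, not just the best chain.
// [[Rcpp::export]]
DataFrame cpp_map_all_chains(CharacterVector seqs, SEXP idxp) {
  XPtr<MinIndex> idx(idxp);
  std::vector<int> o_q, o_t, o_strand, o_score, o_pos;
  std::vector<double> o_cov;
  for (int qi = 0; qi < (int)seqs.size(); ++qi) {
    std::string seq = as<std::string>(seqs[qi]);
    std::string cseq;
    std::vector<int> qmap;
    const std::string* q = &seq;
    if (idx->hpc) { cseq = compress_hp_str(seq, qmap); q = &cseq; }
    int qlen = (int)q->size();
    if (qlen < idx->k) continue;
    std::vector<Mini> mins;
    extract_minimizers_core(*q, idx->w, idx->k, mins);
    std::map<uint64_t, std::vector<std::pair<int,int>>> groups;
    for (const Mini& m : mins) {
      auto it = idx->table.find(m.hash);
      if (it == idx->table.end()) continue;
      if (idx->max_occ > 0 && (int)it->second.size() > idx->max_occ) continue;
      for (uint64_t h : it->second) {
        int t = (int)(h >> 34);
        int tpos = (int)((h >> 2) & ((1ULL << 32) - 1));
        int rel = (m.strand == (int)(h & 1)) ? 0 : 1;
        groups[((uint64_t)t << 1) | rel].push_back(
          {m.pos, rel == 0 ? tpos : -tpos});
      }
    }
    for (auto& kv : groups) {
      std::vector<int> mem;
      int sc = lis_chain(kv.second, &mem);
      if (sc == 0) continue;
      int target = (int)(kv.first >> 1);
      int rel = (int)(kv.first & 1);
      std::vector<int> qs;
      for (int m2 : mem) qs.push_back(kv.second[m2].first);
      std::sort(qs.begin(), qs.end());
      long covered = qs.back() + idx->k - qs.front();
      int qfirst = kv.second[mem.front()].first;
      int qlast = kv.second[mem.back()].first;
      int pos_c;
      if (rel == 0) pos_c = kv.second[mem.front()].second - qfirst;
      else pos_c = -kv.second[mem.back()].second - (qlen - (qlast + idx->k));
      int tlen_c = idx->hpc ? idx->clens[target] : idx->lens[target];
      if (pos_c < 0) pos_c = 0;
      if (pos_c > tlen_c - 1) pos_c = tlen_c - 1;
      int pos = idx->hpc ? idx->hp_maps[target][pos_c] : pos_c;
      o_q.push_back(qi + 1); o_t.push_back(target + 1);
      o_strand.push_back(rel); o_score.push_back(sc); o_pos.push_back(pos);
      o_cov.push_back((double)covered / qlen);
    }
  }
  return DataFrame::create(_["query"] = wrap(o_q), _["target"] = wrap(o_t),
                           _["strand"] = wrap(o_strand),
                           _["score"] = wrap(o_score), _["pos"] = wrap(o_pos),
                           _["covered"] = wrap(o_cov));
}

static inline char cbase(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  default: return 'N';
  }
}

// Fused synthetic-pair extraction + mapping over a batch of long reads.
// For each library insert d <= read length, 250-bp mates are cut at offsets
// 0, step, 2*step, ... (mate2 reverse complemented), both mates mapped, and
// the pair kept iff both have mapq > min_mapq and covered > min_cov.
// Inter-contig pairs are emitted as rows; same-contig pairs feed per-library
// distance moments. Per-contig mapped-mate bases and (read,contig) label
// pairs are accumulated for coverage and the contig labeling function.
// [[Rcpp::export]]
List cpp_map_synthetic(CharacterVector read_seqs, IntegerVector inserts,
                       SEXP idxp, int step, int mate_len,
                       int min_mapq, double min_cov) {
  XPtr<MinIndex> idx(idxp);
  int nlib = (int)inserts.size();
  int ntarg = (int)idx->ids.size();
  std::vector<int> o_read, o_off, o_lib, o_c1, o_v1, o_p1, o_c2, o_v2, o_p2;
  std::vector<int> o_g1, o_g2;
  std::vector<double> covbases(ntarg, 0.0);
  std::vector<int> lab_read, lab_contig;
  std::vector<double> lib_n(nlib, 0), lib_sum(nlib, 0), lib_ss(nlib, 0);
  long n_cand = 0, n_acc = 0, n_same = 0;
  std::vector<Mini> mins;
  std::vector<Anchor> anchors;
  std::string m2(mate_len, 'N');
  std::vector<int> hmap;
  std::string hbuf;
  auto map_span = [&](const char* p2, int n2) -> MapResult {
    if (!idx->hpc) return map_one_span(p2, n2, *idx, mins, anchors);
    hbuf.assign(p2, n2);
    std::string c = compress_hp_str(hbuf, hmap);
    return map_one_span(c.data(), (int)c.size(), *idx, mins, anchors);
  };
  for (int r = 0; r < (int)read_seqs.size(); ++r) {
    std::string rs = as<std::string>(read_seqs[r]);
    int L = (int)rs.size();
    std::vector<std::pair<int,int>> seen; // (read-local) accepted (contig) set
    for (int j = 0; j < nlib; ++j) {
      int d = inserts[j];
      if (d > L || d < 2 * mate_len) continue;
      for (int off = 0; off + d <= L; off += step) {
        ++n_cand;
        MapResult a1 = map_span(rs.data() + off, mate_len);
        if (a1.target < 0 || a1.mapq <= min_mapq || a1.covered <= min_cov)
          continue;
        const char* m2raw = rs.data() + off + d - mate_len;
        for (int t = 0; t < mate_len; ++t) m2[t] = cbase(m2raw[mate_len-1-t]);
        MapResult a2 = map_span(m2.data(), mate_len);
        if (a2.target < 0 || a2.mapq <= min_mapq || a2.covered <= min_cov)
          continue;
        ++n_acc;
        covbases[a1.target] += mate_len;
        covbases[a2.target] += mate_len;
        seen.push_back({r, a1.target});
        seen.push_back({r, a2.target});
        if (a1.target == a2.target) {
          ++n_same;
          double dist = std::abs(a2.pos - a1.pos) + mate_len;
          lib_n[j] += 1; lib_sum[j] += dist; lib_ss[j] += dist * dist;
          continue;
        }
        // orientation-normalized frame: vertex = end the mate points past
        // (head when mapped '+', tail when '-'); pos = distance from the
        // opposite end to the mate's outer boundary
        int l1 = idx->lens[a1.target], l2 = idx->lens[a2.target];
        int v1 = 2 * a1.target + (a1.strand == 0 ? 1 : 0);
        int p1 = a1.strand == 0 ? a1.pos : l1 - (a1.pos + mate_len);
        int v2 = 2 * a2.target + (a2.strand == 0 ? 1 : 0);
        int p2 = a2.strand == 0 ? a2.pos : l2 - (a2.pos + mate_len);
        if (p1 < 0) p1 = 0;
        if (p2 < 0) p2 = 0;
        o_read.push_back(r + 1); o_off.push_back(off); o_lib.push_back(j + 1);
        o_c1.push_back(a1.target + 1); o_v1.push_back(v1 + 1); o_p1.push_back(p1);
        o_c2.push_back(a2.target + 1); o_v2.push_back(v2 + 1); o_p2.push_back(p2);
        // read coordinates of the inter-contig junction: where the fragment
        // leaves contig 1 and where it enters contig 2
        o_g1.push_back(off + (l1 - p1));
        o_g2.push_back(off + d - (l2 - p2));
      }
    }
    std::sort(seen.begin(), seen.end());
    seen.erase(std::unique(seen.begin(), seen.end()), seen.end());
    for (auto& pr : seen) {
      lab_read.push_back(pr.first + 1);
      lab_contig.push_back(pr.second + 1);
    }
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  DataFrame pairs = DataFrame::create(
    _["read"] = wrap(o_read), _["offset"] = wrap(o_off), _["lib"] = wrap(o_lib),
    _["c1"] = wrap(o_c1), _["v1"] = wrap(o_v1), _["pos1"] = wrap(o_p1),
    _["c2"] = wrap(o_c2), _["v2"] = wrap(o_v2), _["pos2"] = wrap(o_p2),
    _["g1"] = wrap(o_g1), _["g2"] = wrap(o_g2));
  DataFrame labels = DataFrame::create(_["read"] = wrap(lab_read),
                                       _["contig"] = wrap(lab_contig));
  DataFrame libstats = DataFrame::create(_["n"] = wrap(lib_n),
                                         _["sum"] = wrap(lib_sum),
                                         _["sumsq"] = wrap(lib_ss));
  return List::create(_["pairs"] = pairs, _["covbases"] = wrap(covbases),
                      _["labels"] = labels, _["lib_stats"] = libstats,
                      _["n_candidate"] = (double)n_cand,
                      _["n_accepted"] = (double)n_acc,
                      _["n_same_contig"] = (double)n_same);
}
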