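#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default:  return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) r[j] = comp_base(s[s.size() - 1 - j]);
    out[i] = r;
  }
  return out;
}

// Uniform random DNA using R's RNG (so set.seed() governs it).
// [[Rcpp::export]]
std::string cpp_random_dna(int n) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string s(n, 'A');
  for (int i = 0; i < n; ++i) s[i] = bases[(int)(unif_rand() * 4) & 3];
  return s;
}

// Per-base substitution at rate `rate`; substituted base drawn from the
// three alternatives.
// [[Rcpp::export]]
std::string cpp_mutate_subs(std::string s, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  for (size_t i = 0; i < s.size(); ++i) {
    if (unif_rand() < rate) {
      char c = s[i];
      char nb = c;
      while (nb == c) nb = bases[(int)(unif_rand() * 4) & 3];
      s[i] = nb;
    }
  }
  return s;
}

// Inject substitutions/insertions/deletions. Indel rates are multiplied by
// hp_bias inside homopolymer runs of length >= 3 (the dominant error mode of
// raw nanopore-like reads). Uses R's RNG.
// [[Rcpp::export]]
std::string cpp_inject_errors(std::string s, double sub, double ins,
                              double del, double hp_bias) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string out;
  out.reserve((size_t)(s.size() * 1.1) + 16);
  size_t n = s.size();
  // homopolymer run membership
  std::vector<uint8_t> in_run(n, 0);
  size_t i = 0;
  while (i < n) {
    size_t j = i;
    while (j < n && s[j] == s[i]) ++j;
    if (j - i >= 3) for (size_t t = i; t < j; ++t) in_run[t] = 1;
    i = j;
  }
  for (size_t p = 0; p < n; ++p) {
    double bias = in_run[p] ? hp_bias : 1.0;
    double d = del * bias, in = ins * bias;
    if (unif_rand() < d) continue;           // deletion
    char c = s[p];
    if (unif_rand() < sub) {
      char nb = c;
      while (nb == c) nb = bases[(int)(unif_rand() * 4) & 3];
      c = nb;
    }
    out.push_back(c);
    if (unif_rand() < in) out.push_back(bases[(int)(unif_rand() * 4) & 3]);
  }
  return out;
}

// Homopolymer compression with a 0-based coordinate map back to run starts.
// [[Rcpp::export]]
List cpp_compress_hp(std::string s) {
  std::string c;
  std::vector<int> map;
  c.reserve(s.size());
  map.reserve(s.size());
  size_t i = 0;
  while (i < s.size()) {
    c.push_back(s[i]);
    map.push_back((int)i);
    size_t j = i;
    while (j < s.size() && s[j] == s[i]) ++j;
    i = j;
  }
  return List::create(_["seq"] = c, _["map"] = wrap(map));
}
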