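// Canonical k-mer counting for digital normalization and pseudo-mapping
// depth estimation. k must be odd and <= 31 (2-bit packing, no canonical
// self-palindromes). K-mers containing ambiguity codes are skipped.
#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Calls f(pos, canonical_kmer) for every valid k-mer (0-based start pos).
template <typename F>
static void for_kmers(const std::string& s, int k, F f) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (int i = 0; i < (int)s.size(); ++i) {
    int c = code(s[i]);
    if (c < 0) { run = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) f(i - k + 1, fwd < rev ? fwd : rev);
  }
}

static std::string decode(uint64_t key, int k) {
  static const char b[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = b[key & 3]; key >>= 2; }
  return s;
}

// Canonical k-mer spectrum over a set of sequences.
// [[Rcpp::export]]
List cpp_kmer_spectrum(CharacterVector seqs, int k) {
  std::unordered_map<uint64_t, int> counts;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for_kmers(s, k, [&](int, uint64_t key) { counts[key]++; });
  }
  std::vector<std::pair<uint64_t, int>> v(counts.begin(), counts.end());
  std::sort(v.begin(), v.end());
  CharacterVector km(v.size());
  IntegerVector ct(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    km[i] = decode(v[i].first, k);
    ct[i] = v[i].second;
  }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

// Two-pass pair statistic for digital normalization: pass 1 counts canonical
// k-mers over all mates; pass 2 returns, per pair, the median count over the
// k-mers of both mates (NA if a pair yields no valid k-mer).
// [[Rcpp::export]]
NumericVector cpp_pair_median_kmer(CharacterVector r1, CharacterVector r2, int k) {
  std::unordered_map<uint64_t, int> counts;
  for (R_xlen_t i = 0; i < r1.size(); ++i) {
    for_kmers(as<std::string>(r1[i]), k, [&](int, uint64_t key) { counts[key]++; });
    for_kmers(as<std::string>(r2[i]), k, [&](int, uint64_t key) { counts[key]++; });
  }
  NumericVector med(r1.size());
  std::vector<int> buf;
  for (R_xlen_t i = 0; i < r1.size(); ++i) {
    buf.clear();
    for_kmers(as<std::string>(r1[i]), k, [&](int, uint64_t key) { buf.push_back(counts[key]); });
    for_kmers(as<std::string>(r2[i]), k, [&](int, uint64_t key) { buf.push_back(counts[key]); });
    if (buf.empty()) { med[i] = NA_REAL; continue; }
    std::sort(buf.begin(), buf.end());
    size_t n = buf.size();
    med[i] = (n % 2) ? buf[n / 2] : (buf[n / 2 - 1] + buf[n / 2]) / 2.0;
  }
  return med;
}

// Pseudo-mapping depth: per read, every canonical read k-mer that occurs
// exactly once in the assembly marks the k assembly bases it covers; the
// union of marked bases (the read's k-mer cover) gains one unit of depth.
// A full-length error-free read therefore contributes 1x over its span.
// [[Rcpp::export]]
IntegerVector cpp_depth(CharacterVector reads, std::string assembly, int k) {
  const int n = (int)assembly.size();
  // canonical k-mer -> (first position, count) in the assembly
  std::unordered_map<uint64_t, std::pair<int, int>> idx;
  for_kmers(assembly, k, [&](int pos, uint64_t key) {
    auto it = idx.find(key);
    if (it == idx.end()) idx[key] = {pos, 1};
    else it->second.second++;
  });
  std::vector<int> diff(n + 1, 0);
  std::vector<std::pair<int, int>> iv;  // per-read covered intervals
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    iv.clear();
    for_kmers(as<std::string>(reads[i]), k, [&](int, uint64_t key) {
      auto it = idx.find(key);
      if (it != idx.end() && it->second.second == 1)
        iv.push_back({it->second.first, it->second.first + k});
    });
    if (iv.empty()) continue;
    std::sort(iv.begin(), iv.end());
    int s = iv[0].first, e = iv[0].second;
    for (size_t j = 1; j < iv.size(); ++j) {
      if (iv[j].first <= e) { e = std::max(e, iv[j].second); continue; }
      diff[s] += 1; diff[e] -= 1;
      s = iv[j].first; e = iv[j].second;
    }
    diff[s] += 1; diff[e] -= 1;
  }
  IntegerVector depth(n);
  int acc = 0;
  for (int i = 0; i < n; ++i) { acc += diff[i]; depth[i] = acc; }
  return depth;
}
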