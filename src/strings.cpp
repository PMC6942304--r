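// Exact-match string machinery: matching statistics over a suffix automaton,
// maximal exact matches (MEMs) and maximal repeat pairs via seeded
// left-maximal extension. Coordinates here are 0-based half-open; the R
// wrappers convert to 1-based IRanges convention.
#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <set>
#include <tuple>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// DNA codes: A=0 C=1 G=2 T=3; every other character (IUPAC ambiguity) = -1
// and never matches anything in exact-match operations.
static inline int code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline bool eqc(int a, int b) { return a >= 0 && a == b; }

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = code(s[i]);
  return v;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      default: c = 'N'; break;  // ambiguity stays non-matching
    }
  }
  return r;
}

// ---------------------------------------------------------------------------
// Suffix automaton over the 5-letter alphabet {A,C,G,T,SEP}. SEP (code 4)
// separates concatenated subjects and stands in for ambiguity codes, so no
// match can cross them (a query never emits SEP).
struct SAM {
  std::vector<std::array<int, 5>> nxt;
  std::vector<int> link, len;
  int last;

  explicit SAM(size_t cap) {
    nxt.reserve(2 * cap + 4); link.reserve(2 * cap + 4); len.reserve(2 * cap + 4);
    nxt.push_back({{-1, -1, -1, -1, -1}});
    link.push_back(-1); len.push_back(0);
    last = 0;
  }
  int add_state(int l) {
    nxt.push_back({{-1, -1, -1, -1, -1}});
    link.push_back(-1); len.push_back(l);
    return (int)nxt.size() - 1;
  }
  void extend(int c) {
    int cur = add_state(len[last] + 1);
    int p = last;
    while (p != -1 && nxt[p][c] == -1) { nxt[p][c] = cur; p = link[p]; }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = nxt[p][c];
      if (len[p] + 1 == len[q]) {
        link[cur] = q;
      } else {
        int clone = add_state(len[p] + 1);
        nxt[clone] = nxt[q];
        link[clone] = link[q];
        while (p != -1 && nxt[p][c] == q) { nxt[p][c] = clone; p = link[p]; }
        link[q] = clone; link[cur] = clone;
      }
    }
    last = cur;
  }
};

// Suffix automaton of the REVERSED subject (plus, optionally, the reversed
// opposite strand): X is a substring of S iff rev(X) is one of rev(S), and
// rev(revcomp(S)) == complement(S).
static SAM sam_of_reversed(const std::string& subject, bool both_strands) {
  std::string textR(subject.rbegin(), subject.rend());
  if (both_strands) {
    std::string comp = subject;
    for (auto& c : comp) {
      switch (c) {
        case 'A': c = 'T'; break; case 'C': c = 'G'; break;
        case 'G': c = 'C'; break; case 'T': c = 'A'; break;
        default: c = 'N'; break;
      }
    }
    textR.push_back('#');
    textR += comp;
  }
  SAM sam(textR.size());
  for (char ch : textR) {
    int c = code(ch);
    sam.extend(c < 0 ? 4 : c);
  }
  return sam;
}

// Stream the reversed query over the automaton; ms[i] = longest prefix of
// query[i:] occurring in the subject.
static std::vector<int> stream_ms(const std::string& query, const SAM& sam) {
  const size_t m = query.size();
  std::vector<int> ms(m);
  int cur = 0, l = 0;
  for (size_t t = 0; t < m; ++t) {
    size_t i = m - 1 - t;  // original query index, processed in reverse
    int c = code(query[i]);
    if (c < 0) { cur = 0; l = 0; ms[i] = 0; continue; }
    if (sam.nxt[cur][c] != -1) {
      cur = sam.nxt[cur][c]; ++l;
    } else {
      int p = cur;
      while (p != -1 && sam.nxt[p][c] == -1) p = sam.link[p];
      if (p == -1) { cur = 0; l = 0; }
      else { l = sam.len[p] + 1; cur = sam.nxt[p][c]; }
    }
    ms[i] = l;
  }
  return ms;
}

// Matching statistics of one query against one subject.
// [[Rcpp::export]]
IntegerVector cpp_matching_stats(std::string query, std::string subject,
                                 bool both_strands) {
  SAM sam = sam_of_reversed(subject, both_strands);
  return wrap(stream_ms(query, sam));
}

// Batched mean floored matching statistics: L[i,j] = mean over positions of
// max(ms(query_i vs subject_j), 1). Each subject automaton is built once and
// streamed by every query, which is what makes database-wide ACS ranking
// cheap.
// [[Rcpp::export]]
NumericMatrix cpp_acs_lbar(CharacterVector queries, CharacterVector subjects,
                           bool both_strands) {
  NumericMatrix L(queries.size(), subjects.size());
  std::vector<std::string> qs(queries.size());
  for (R_xlen_t i = 0; i < queries.size(); ++i)
    qs[i] = as<std::string>(queries[i]);
  for (R_xlen_t j = 0; j < subjects.size(); ++j) {
    SAM sam = sam_of_reversed(as<std::string>(subjects[j]), both_strands);
    for (R_xlen_t i = 0; i < (R_xlen_t)qs.size(); ++i) {
      std::vector<int> ms = stream_ms(qs[i], sam);
      double acc = 0;
      for (int v : ms) acc += v < 1 ? 1 : v;
      L(i, j) = acc / (double)ms.size();
    }
  }
  return L;
}

// ---------------------------------------------------------------------------
// MEM enumeration by seed hashing + left-maximal right extension. A MEM of
// length >= min_len contains a seed (first min(min_len,31) bases) at its
// left-maximal start; we record it exactly there, exactly once.
struct Mem { int q, s, l; };

static void mems_one(const std::vector<int>& q, const std::vector<int>& s,
                     int min_len, std::vector<Mem>& out) {
  const int seed = min_len < 31 ? min_len : 31;
  const int qn = (int)q.size(), sn = (int)s.size();
  if (qn < min_len || sn < min_len) return;
  std::unordered_map<uint64_t, std::vector<int>> idx;
  idx.reserve(sn);
  {
    uint64_t key = 0; int run = 0;
    const uint64_t mask = (seed < 32) ? ((1ULL << (2 * seed)) - 1) : ~0ULL;
    for (int j = 0; j < sn; ++j) {
      if (s[j] < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)s[j]) & mask;
      if (++run >= seed) idx[key].push_back(j - seed + 1);
    }
  }
  uint64_t key = 0; int run = 0;
  const uint64_t mask = (seed < 32) ? ((1ULL << (2 * seed)) - 1) : ~0ULL;
  for (int e = 0; e < qn; ++e) {
    if (q[e] < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)q[e]) & mask;
    if (++run < seed) continue;
    const int i = e - seed + 1;
    auto it = idx.find(key);
    if (it == idx.end()) continue;
    for (int j : it->second) {
      if (i > 0 && j > 0 && eqc(q[i - 1], s[j - 1])) continue;  // not left-maximal
      int l = seed;
      while (i + l < qn && j + l < sn && eqc(q[i + l], s[j + l])) ++l;
      if (l >= min_len) out.push_back({i, j, l});
    }
  }
}

// All MEMs between query and subject, both strands. s_start is the start of
// the matched interval on the subject TOP strand, 0-based.
// [[Rcpp::export]]
DataFrame cpp_mems(std::string query, std::string subject, int min_len,
                   bool both_strands) {
  std::vector<int> q = encode(query), s = encode(subject);
  std::vector<Mem> fwd, rev;
  mems_one(q, s, min_len, fwd);
  if (both_strands) {
    std::vector<int> src = encode(revcomp(subject));
    mems_one(q, src, min_len, rev);
  }
  const int sn = (int)s.size();
  size_t n = fwd.size() + rev.size();
  IntegerVector qs(n), ss(n), ln(n);
  CharacterVector st(n);
  size_t r = 0;
  for (const Mem& m : fwd) { qs[r] = m.q; ss[r] = m.s; ln[r] = m.l; st[r] = "+"; ++r; }
  for (const Mem& m : rev) { qs[r] = m.q; ss[r] = sn - m.s - m.l; ln[r] = m.l; st[r] = "-"; ++r; }
  return DataFrame::create(_["q_start"] = qs, _["s_start"] = ss,
                           _["length"] = ln, _["strand"] = st);
}

// Maximal repeated pairs within one sequence: direct (i<j) and, optionally,
// inverted (second interval = reverse complement of the first). The trivial
// self pair is excluded. Intervals are 0-based starts with a shared length.
// [[Rcpp::export]]
DataFrame cpp_maximal_repeats(std::string seq, int min_len, bool include_revcomp) {
  std::vector<int> s = encode(seq);
  const int n = (int)s.size();
  std::set<std::tuple<int, int, int, bool>> pairs;  // start1, start2, len, inverted
  {
    std::vector<Mem> self;
    mems_one(s, s, min_len, self);
    for (const Mem& m : self)
      if (m.q < m.s) pairs.insert({m.q, m.s, m.l, false});
  }
  if (include_revcomp) {
    std::vector<int> rc = encode(revcomp(seq));
    std::vector<Mem> inv;
    mems_one(s, rc, min_len, inv);
    for (const Mem& m : inv) {
      int a = m.q, b = n - m.s - m.l;
      if (a == b) continue;  // an interval equal to its own revcomp is not a pair
      if (a > b) std::swap(a, b);
      pairs.insert({a, b, m.l, true});
    }
  }
  size_t np = pairs.size();
  IntegerVector s1(np), s2(np), ln(np);
  LogicalVector iv(np);
  size_t r = 0;
  for (const auto& p : pairs) {
    s1[r] = std::get<0>(p); s2[r] = std::get<1>(p);
    ln[r] = std::get<2>(p); iv[r] = std::get<3>(p); ++r;
  }
  return DataFrame::create(_["start1"] = s1, _["start2"] = s2,
                           _["length"] = ln, _["inverted"] = iv);
}
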