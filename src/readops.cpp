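// Read-level operations: 3' adapter trimming (suffix-overlap model, no
// indels), paired-end overlap detection, and IUPAC-aware primer site
// scanning for simulated PCR.
#include <Rcpp.h>
#include <cmath>
#include <string>
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
static inline bool eqc(int a, int b) { return a >= 0 && a == b; }

// Best-scoring suffix-overlapping-prefix adapter occurrence per read.
// Placement p aligns adapter[0..L) with read[p..p+L), L = min(alen, rlen-p);
// valid if L >= min_overlap and mismatches <= floor(max_error_rate*L).
// Among valid placements the one with most matching bases wins, ties to the
// leftmost (longest trim). Returns the kept length p (rlen if no occurrence).
// [[Rcpp::export]]
IntegerVector cpp_trim_positions(CharacterVector seqs, std::string adapter,
                                 int min_overlap, double max_error_rate) {
  const int alen = (int)adapter.size();
  std::vector<int> a(alen);
  for (int i = 0; i < alen; ++i) a[i] = code(adapter[i]);
  IntegerVector keep(seqs.size());
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    const int rlen = (int)s.size();
    int best_score = -1, best_p = rlen;
    for (int p = 0; p <= rlen - min_overlap; ++p) {
      int L = std::min(alen, rlen - p);
      if (L < min_overlap) break;
      int allowed = (int)std::floor(max_error_rate * L);
      int mm = 0;
      for (int i = 0; i < L && mm <= allowed; ++i)
        if (!eqc(code(s[p + i]), a[i])) ++mm;
      if (mm > allowed) continue;
      int score = L - mm;
      if (score > best_score) { best_score = score; best_p = p; }
    }
    keep[r] = best_p;
  }
  return keep;
}

// Paired-end overlap: r2rc is mate 2 already reverse-complemented into
// fragment orientation. Candidate overlap o aligns the o-suffix of r1 with
// the o-prefix of r2rc; valid if o >= min_overlap and mismatches <=
// floor(max_mismatch_rate*o). Score = matching bases (o - mm); a tie between
// two distinct overlap lengths is flagged ambiguous. Returns per pair:
// olen (0 = no merge), mm, ambiguous.
// [[Rcpp::export]]
DataFrame cpp_overlap_merge(CharacterVector r1, CharacterVector r2rc,
                            int min_overlap, double max_mismatch_rate) {
  R_xlen_t n = r1.size();
  IntegerVector olen(n), mmv(n);
  LogicalVector amb(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string a = as<std::string>(r1[r]), b = as<std::string>(r2rc[r]);
    const int l1 = (int)a.size(), l2 = (int)b.size();
    int best_score = -1, best_o = 0, best_mm = 0, n_best = 0;
    for (int o = min_overlap; o <= std::min(l1, l2); ++o) {
      int allowed = (int)std::floor(max_mismatch_rate * o);
      int mm = 0;
      for (int i = 0; i < o && mm <= allowed; ++i)
        if (!eqc(code(a[l1 - o + i]), code(b[i]))) ++mm;
      if (mm > allowed) continue;
      int score = o - mm;
      if (score > best_score) { best_score = score; best_o = o; best_mm = mm; n_best = 1; }
      else if (score == best_score) ++n_best;
    }
    olen[r] = best_o; mmv[r] = best_mm; amb[r] = (n_best > 1);
  }
  return DataFrame::create(_["olen"] = olen, _["mm"] = mmv, _["ambiguous"] = amb);
}

// IUPAC possibility-set bitmasks. Template N is deliberately the empty set:
// a fully ambiguous template base (e.g. an N-filled gap) binds no primer.
static int iupac_mask(char c, bool is_template) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 5;   // A/G
    case 'Y': case 'y': return 10;  // C/T
    case 'S': case 's': return 6;   // G/C
    case 'W': case 'w': return 9;   // A/T
    case 'K': case 'k': return 12;  // G/T
    case 'M': case 'm': return 3;   // A/C
    case 'B': case 'b': return 14;  // C/G/T
    case 'D': case 'd': return 13;  // A/G/T
    case 'H': case 'h': return 11;  // A/C/T
    case 'V': case 'v': return 7;   // A/C/G
    case 'N': case 'n': return is_template ? 0 : 15;
    default: return 0;
  }
}

// All template positions (0-based) where the primer binds in forward
// orientation: <= max_mismatch mismatching positions, the 3 bases at the
// primer 3' end mismatch-free. A mismatch is an empty intersection of the
// primer and template possibility sets.
// [[Rcpp::export]]
DataFrame cpp_pcr_sites(std::string templ, std::string primer, int max_mismatch) {
  const int n = (int)templ.size(), p = (int)primer.size();
  std::vector<int> tm(n), pm(p);
  for (int i = 0; i < n; ++i) tm[i] = iupac_mask(templ[i], true);
  for (int i = 0; i < p; ++i) pm[i] = iupac_mask(primer[i], false);
  std::vector<int> pos;
  std::vector<int> mms;
  for (int t = 0; t + p <= n; ++t) {
    int mm = 0;
    bool ok = true;
    for (int i = 0; i < p; ++i) {
      if ((pm[i] & tm[t + i]) == 0) {
        if (i >= p - 3) { ok = false; break; }  // 3' anchor must be exact
        if (++mm > max_mismatch) { ok = false; break; }
      }
    }
    if (ok) { pos.push_back(t); mms.push_back(mm); }
  }
  return DataFrame::create(_["pos"] = wrap(pos), _["mismatches"] = wrap(mms));
}
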