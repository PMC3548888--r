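#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Exact-match occurrence scanning over a set of uppercase sequences.
// A query position matches only on identical {A,C,G,T} characters; any
// other character (N, IUPAC ambiguity) never matches, so windows that
// contain one are unmatchable. Minus-strand matches are matches of the
// reverse complement of the query on the forward representation.

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return '\0';  // never matches anything
  }
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static bool query_valid(const char *q, int L) {
  for (int i = 0; i < L; ++i) if (!valid_base(q[i])) return false;
  return true;
}

// Count forward-strand matches of q in s; stop once count reaches cap
// (cap <= 0 means unbounded).
static int count_fwd(const char *s, int n, const char *q, int L, int cap,
                     std::vector<int> *hits = nullptr) {
  int count = 0;
  for (int i = 0; i + L <= n; ++i) {
    if (std::memcmp(s + i, q, (size_t)L) == 0) {
      ++count;
      if (hits) hits->push_back(i);
      if (cap > 0 && count >= cap) return count;
    }
  }
  return count;
}

// Count matches of revcomp(q) in s (i.e. minus-strand matches of q).
static int count_rc(const char *s, int n, const char *q, int L, int cap,
                    std::vector<int> *hits = nullptr) {
  int count = 0;
  for (int i = 0; i + L <= n; ++i) {
    bool ok = true;
    for (int t = 0; t < L; ++t) {
      if (s[i + t] != comp_base(q[L - 1 - t])) { ok = false; break; }
    }
    if (ok) {
      ++count;
      if (hits) hits->push_back(i);
      if (cap > 0 && count >= cap) return count;
    }
  }
  return count;
}

struct SeqView {
  const char *p;
  int n;
};

static std::vector<SeqView> views(const CharacterVector &seqs) {
  std::vector<SeqView> v(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    v[i] = SeqView{s, (int)std::strlen(s)};
  }
  return v;
}

// [[Rcpp::export]]
int cpp_count_occurrences(CharacterVector seqs, std::string query,
                          bool both_strands, int cap = 0) {
  const int L = (int)query.size();
  if (L == 0 || !query_valid(query.c_str(), L)) return 0;
  std::vector<SeqView> sv = views(seqs);
  int count = 0;
  for (const SeqView &s : sv) {
    int rem = cap > 0 ? cap - count : 0;
    count += count_fwd(s.p, s.n, query.c_str(), L, rem);
    if (cap > 0 && count >= cap) return count;
    if (both_strands) {
      rem = cap > 0 ? cap - count : 0;
      count += count_rc(s.p, s.n, query.c_str(), L, rem);
      if (cap > 0 && count >= cap) return count;
    }
  }
  return count;
}

// [[Rcpp::export]]
List cpp_find_occurrences(CharacterVector seqs, std::string query,
                          bool both_strands) {
  const int L = (int)query.size();
  std::vector<int> seq_idx, pos;
  std::vector<bool> fwd;
  if (L > 0 && query_valid(query.c_str(), L)) {
    std::vector<SeqView> sv = views(seqs);
    for (size_t k = 0; k < sv.size(); ++k) {
      std::vector<int> hf, hr;
      count_fwd(sv[k].p, sv[k].n, query.c_str(), L, 0, &hf);
      if (both_strands) count_rc(sv[k].p, sv[k].n, query.c_str(), L, 0, &hr);
      // merge per sequence sorted by position, '+' before '-' on ties
      size_t a = 0, b = 0;
      while (a < hf.size() || b < hr.size()) {
        bool take_f = b >= hr.size() || (a < hf.size() && hf[a] <= hr[b]);
        seq_idx.push_back((int)k + 1);
        pos.push_back(take_f ? hf[a] : hr[b]);
        fwd.push_back(take_f);
        if (take_f) ++a; else ++b;
      }
    }
  }
  return List::create(_["seq_idx"] = wrap(seq_idx), _["position"] = wrap(pos),
                      _["forward"] = wrap(fwd));
}

// Length of the run of A/C/G/T characters starting at s[p].
static int valid_run(const char *s, int n, int p) {
  int v = 0;
  while (p + v < n && valid_base(s[p + v])) ++v;
  return v;
}

static inline bool unique_at(const std::vector<SeqView> &sv, const char *q,
                             int L, bool both) {
  int count = 0;
  for (const SeqView &s : sv) {
    count += count_fwd(s.p, s.n, q, L, 2 - count);
    if (count >= 2) return false;
    if (both) {
      count += count_rc(s.p, s.n, q, L, 2 - count);
      if (count >= 2) return false;
    }
  }
  return count == 1;
}

// Minimum unique length per position of seqs[[target]] over [p_begin, p_end).
// Bracketing search: probe the longest fitting window, then kmin, then
// ascend in `step` increments to bracket the answer, then scan linearly.
// [[Rcpp::export]]
IntegerVector cpp_mul_array(CharacterVector seqs, int target, int kmin,
                            int kmax, bool both_strands, int step,
                            int p_begin, int p_end) {
  std::vector<SeqView> sv = views(seqs);
  const SeqView tg = sv[target - 1];
  IntegerVector out(p_end - p_begin);
  for (int p = p_begin; p < p_end; ++p) {
    const char *q = tg.p + p;
    int lmax = std::min(kmax, valid_run(tg.p, tg.n, p));
    int &val = out[p - p_begin];
    val = 0;
    if (lmax < kmin) continue;
    if (!unique_at(sv, q, lmax, both_strands)) continue;  // 0: never unique
    if (unique_at(sv, q, kmin, both_strands)) { val = kmin; continue; }
    int klow = kmin, khigh = lmax;
    for (int k = kmin + step; k < lmax; k += step) {
      if (unique_at(sv, q, k, both_strands)) { khigh = k; break; }
      klow = k;
    }
    int m = khigh;
    for (int k = klow + 1; k < khigh; ++k) {
      if (unique_at(sv, q, k, both_strands)) { m = k; break; }
    }
    val = m;
  }
  return out;
}
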