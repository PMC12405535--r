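#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Unit-score global (Needleman-Wunsch) and fitting alignments used across the
// package: barcode clustering, long-read/sensor matching and tail/barcode
// matching. Scores are match +1, mismatch -1, gap -1. 'N' never matches.

struct AlnStats {
  int matches;
  int cols;
  int start;  // 1-based first text position consumed (fitting only)
  int end;    // 1-based last text position consumed (fitting only)
  int score;
};

static inline bool base_match(char a, char b) {
  return a == b && a != 'N' && a != 'n';
}

// Global alignment of a vs b; traceback prefers diagonal, then up (gap in b),
// then left, which makes the reported identity deterministic.
static AlnStats nw_core(const std::string& a, const std::string& b) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = -j; tb[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = -i; tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int sd = prev[j - 1] + (base_match(a[i - 1], b[j - 1]) ? 1 : -1);
      int su = prev[j] - 1;
      int sl = cur[j - 1] - 1;
      int best = sd; unsigned char t = 0;
      if (su > best) { best = su; t = 1; }
      if (sl > best) { best = sl; t = 2; }
      cur[j] = best; tb[(size_t)i * (m + 1) + j] = t;
    }
    std::swap(prev, cur);
  }
  int i = n, j = m, matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && t == 0) {
      if (base_match(a[i - 1], b[j - 1])) ++matches;
      --i; --j;
    } else if (i > 0 && (t == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
    ++cols;
  }
  AlnStats s; s.matches = matches; s.cols = cols; s.start = 1; s.end = m;
  s.score = prev[m];
  return s;
}

// Overlap (end-gap-free / semi-global) alignment of pattern p against text
// t: leading and trailing gaps of both sequences are free. Returns identity
// statistics over the aligned span plus the text coordinates it covers, so
// callers can cut off the tail that extends past the pattern. When the
// optimum ends on the last text column (text exhausted inside the pattern)
// `end` equals the text length and the tail is empty.
static AlnStats fit_core(const std::string& p, const std::string& t) {
  const int n = (int)p.size(), m = (int)t.size();
  std::vector<int> dp((size_t)(n + 1) * (m + 1));
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { dp[j] = 0; tb[j] = 3; }
  for (int i = 1; i <= n; ++i) {
    dp[(size_t)i * (m + 1)] = 0; tb[(size_t)i * (m + 1)] = 3;
    for (int j = 1; j <= m; ++j) {
      int sd = dp[(size_t)(i - 1) * (m + 1) + (j - 1)] +
        (base_match(p[i - 1], t[j - 1]) ? 1 : -1);
      int su = dp[(size_t)(i - 1) * (m + 1) + j] - 1;
      int sl = dp[(size_t)i * (m + 1) + (j - 1)] - 1;
      int best = sd; unsigned char tt = 0;
      if (su > best) { best = su; tt = 1; }
      if (sl > best) { best = sl; tt = 2; }
      dp[(size_t)i * (m + 1) + j] = best; tb[(size_t)i * (m + 1) + j] = tt;
    }
  }
  // best over last row (pattern consumed; leftmost preferred) then last
  // column (text consumed)
  int bi = n, bj = 0, bestsc = dp[(size_t)n * (m + 1)];
  for (int j = 1; j <= m; ++j) {
    if (dp[(size_t)n * (m + 1) + j] > bestsc) {
      bestsc = dp[(size_t)n * (m + 1) + j]; bj = j;
    }
  }
  for (int i = 0; i < n; ++i) {
    if (dp[(size_t)i * (m + 1) + m] > bestsc) {
      bestsc = dp[(size_t)i * (m + 1) + m]; bi = i; bj = m;
    }
  }
  int i = bi, j = bj, matches = 0, cols = 0;
  while (i > 0 && j > 0) {
    unsigned char tt = tb[(size_t)i * (m + 1) + j];
    if (tt == 3) break;
    if (tt == 0) {
      if (base_match(p[i - 1], t[j - 1])) ++matches;
      --i; --j; ++cols;
    } else if (tt == 1) {
      --i; ++cols;
    } else {
      --j; ++cols;
    }
  }
  AlnStats s; s.matches = matches; s.cols = cols; s.start = j + 1;
  s.end = (bi == n) ? bj : m;
  s.score = bestsc;
  return s;
}

// [[Rcpp::export]]
IntegerVector cpp_nw_stats(std::string a, std::string b) {
  AlnStats s = nw_core(a, b);
  return IntegerVector::create(_["matches"] = s.matches, _["cols"] = s.cols,
                               _["score"] = s.score);
}

// [[Rcpp::export]]
IntegerVector cpp_fit_stats(std::string pattern, std::string text) {
  AlnStats s = fit_core(pattern, text);
  return IntegerVector::create(_["matches"] = s.matches, _["cols"] = s.cols,
                               _["start"] = s.start, _["end"] = s.end,
                               _["score"] = s.score);
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("hamming distance requires equal lengths");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (!base_match(a[i], b[i])) ++d;
  return d;
}

// ---- k-mer utilities ------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Sorted multiset of k-mer codes (windows containing non-ACGT skipped).
static void kmer_multiset(const std::string& s, int k, std::vector<uint64_t>& out) {
  out.clear();
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t code = 0; int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++valid >= k) out.push_back(code);
  }
  std::sort(out.begin(), out.end());
}

static int shared_multiset(const std::vector<uint64_t>& x, const std::vector<uint64_t>& y) {
  size_t i = 0, j = 0; int n = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] < y[j]) ++i;
    else if (y[j] < x[i]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}

// ---- greedy centroid clustering ------------------------------------------

// seqs must be sorted by descending count then lexicographic. Each sequence
// joins the FIRST (oldest) centroid with global identity >= threshold, else
// founds a new centroid. Returns, for each sequence, the 1-based index of its
// centroid within seqs. A q-gram lower bound on edit distance and a Hamming
// shortcut avoid most full alignments.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold) {
  const int q = 8;
  const int n = seqs.size();
  IntegerVector res(n);
  std::vector<int> centroids;                 // indices into seqs
  std::vector<std::vector<uint64_t> > ckmers; // q-gram multisets of centroids
  std::vector<std::string> cseq;
  std::vector<uint64_t> qk;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    kmer_multiset(s, q, qk);
    int hit = -1;
    for (size_t c = 0; c < centroids.size(); ++c) {
      const std::string& cs = cseq[c];
      int la = (int)s.size(), lb = (int)cs.size();
      int maxlen = std::max(la, lb), minlen = std::min(la, lb);
      // identity >= t implies edit distance <= (1-t)*maxlen/t
      int dmax = (int)std::floor((1.0 - threshold) * maxlen / threshold + 1e-9);
      if (std::abs(la - lb) > dmax) continue;
      int qbound = (minlen - q + 1) - q * dmax;
      if (qbound > 0 && shared_multiset(qk, ckmers[c]) < qbound) continue;
      if (la == lb) {
        int hd = 0; bool ok = false;
        for (int p = 0; p < la; ++p) if (!base_match(s[p], cs[p])) ++hd;
        // substitution-only identity is a lower bound on NW identity
        if ((double)(la - hd) / la >= threshold) ok = true;
        if (ok) { hit = (int)c; break; }
        if (hd > dmax) continue;  // edit distance > dmax => identity < t
      }
      AlnStats st = nw_core(s, cs);
      if ((double)st.matches / st.cols >= threshold) { hit = (int)c; break; }
    }
    if (hit >= 0) {
      res[i] = centroids[hit] + 1;
    } else {
      centroids.push_back(i);
      ckmers.push_back(qk);
      cseq.push_back(s);
      res[i] = i + 1;
    }
  }
  return res;
}

// ---- seeded fitting alignment of queries against references ---------------

// For each query, candidate references are ranked by the number of distinct
// shared k-mers, the top_n candidates are aligned with the overlap alignment
// and the best score wins. A score tie between two references reports
// tie = TRUE.
// [[Rcpp::export]]
List cpp_seed_fit_align(CharacterVector queries, CharacterVector refs,
                        int k, int top_n) {
  const int nq = queries.size(), nr = refs.size();
  std::vector<std::string> rseq(nr);
  std::unordered_map<uint64_t, std::vector<int> > index;
  std::vector<uint64_t> km;
  for (int r = 0; r < nr; ++r) {
    rseq[r] = as<std::string>(refs[r]);
    kmer_multiset(rseq[r], k, km);
    km.erase(std::unique(km.begin(), km.end()), km.end());
    for (size_t t = 0; t < km.size(); ++t) {
      std::vector<int>& v = index[km[t]];
      if (v.empty() || v.back() != r) v.push_back(r);
    }
  }
  IntegerVector ref_idx(nq), endpos(nq), startpos(nq), n_cand(nq);
  NumericVector identity(nq);
  LogicalVector tie(nq);
  std::vector<int> counts(nr, 0), touched;
  for (int qi = 0; qi < nq; ++qi) {
    std::string qs = as<std::string>(queries[qi]);
    kmer_multiset(qs, k, km);
    km.erase(std::unique(km.begin(), km.end()), km.end());
    touched.clear();
    for (size_t t = 0; t < km.size(); ++t) {
      std::unordered_map<uint64_t, std::vector<int> >::iterator it = index.find(km[t]);
      if (it == index.end()) continue;
      for (size_t u = 0; u < it->second.size(); ++u) {
        int r = it->second[u];
        if (counts[r] == 0) touched.push_back(r);
        ++counts[r];
      }
    }
    std::sort(touched.begin(), touched.end(),
              [&](int a, int b) {
                if (counts[a] != counts[b]) return counts[a] > counts[b];
                return a < b;
              });
    int ncand = std::min((int)touched.size(), top_n);
    n_cand[qi] = (int)touched.size();
    int best_r = -1; AlnStats best_st; best_st.score = 0;
    bool tied = false;
    for (int ci = 0; ci < ncand; ++ci) {
      int r = touched[ci];
      AlnStats st = fit_core(rseq[r], qs);
      if (best_r < 0 || st.score > best_st.score) {
        best_r = r; best_st = st; tied = false;
      } else if (st.score == best_st.score) {
        tied = true;
      }
    }
    for (size_t t = 0; t < touched.size(); ++t) counts[touched[t]] = 0;
    if (best_r < 0) {
      ref_idx[qi] = 0; identity[qi] = NA_REAL; endpos[qi] = 0; startpos[qi] = 0;
      tie[qi] = false;
    } else {
      ref_idx[qi] = best_r + 1;
      identity[qi] = best_st.cols > 0 ?
        (double)best_st.matches / (double)best_st.cols : 0.0;
      endpos[qi] = best_st.end;
      startpos[qi] = best_st.start;
      tie[qi] = tied;
    }
  }
  return List::create(_["ref_idx"] = ref_idx, _["identity"] = identity,
                      _["start"] = startpos, _["end"] = endpos,
                      _["tie"] = tie, _["n_candidates"] = n_cand);
}

// ---- rejection-sampling support -------------------------------------------

// TRUE if candidate has global identity >= threshold to any accepted sequence.
// [[Rcpp::export]]
bool cpp_any_identity_ge(std::string candidate, CharacterVector accepted,
                         double threshold) {
  for (int i = 0; i < accepted.size(); ++i) {
    std::string a = as<std::string>(accepted[i]);
    AlnStats st = nw_core(candidate, a);
    if ((double)st.matches / st.cols >= threshold) return true;
  }
  return false;
}

// ---- read error model ------------------------------------------------------

// Per-base substitutions at sub_rate plus insertions/deletions at indel_rate
// (split evenly) with geometric length (continuation probability indel_ext).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_mutate_reads(CharacterVector seqs, double sub_rate,
                                 double indel_rate, double indel_ext) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  RNGScope scope;
  const int n = seqs.size();
  CharacterVector out(n);
  std::string res;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    res.clear();
    res.reserve(s.size() + 16);
    size_t p = 0;
    while (p < s.size()) {
      double u = unif_rand();
      if (u < sub_rate) {
        int b = base_code(s[p]);
        int nb = (int)(unif_rand() * 3.0); if (nb > 2) nb = 2;
        if (b >= 0) {
          // pick one of the three other bases
          int pick = (b + 1 + nb) % 4;
          res.push_back(BASES[pick]);
        } else {
          res.push_back(s[p]);
        }
        ++p;
      } else if (u < sub_rate + indel_rate) {
        int len = 1;
        while (unif_rand() < indel_ext) ++len;
        if (unif_rand() < 0.5) {
          p += (size_t)len;  // deletion
        } else {
          for (int t = 0; t < len; ++t) {
            int nb = (int)(unif_rand() * 4.0); if (nb > 3) nb = 3;
            res.push_back(BASES[nb]);
          }
          res.push_back(s[p]);
          ++p;
        }
      } else {
        res.push_back(s[p]);
        ++p;
      }
    }
    out[i] = res;
  }
  return out;
}

// ---- adapter trimming ------------------------------------------------------

static int overlap_mismatches(const std::string& read, const std::string& adapter,
                              int p /*0-based start of adapter in read, may be <0*/,
                              int& overlap) {
  int mm = 0; overlap = 0;
  int A = (int)adapter.size(), L = (int)read.size();
  for (int t = 0; t < A; ++t) {
    int rp = p + t;
    if (rp < 0 || rp >= L) continue;
    ++overlap;
    if (!base_match(read[rp], adapter[t])) ++mm;
  }
  return mm;
}

// Trims one leading and one trailing adapter occurrence. An occurrence may
// overhang the read end provided >= min_match bases overlap and it carries
// <= max_mismatch mismatches; mismatches must additionally stay below a
// quarter of the overlap, so that short partial overlaps cannot be satisfied
// by random sequence. The best-scoring (overlap - mismatches) occurrence
// near each end is removed. Returns the trimmed sequences.
// [[Rcpp::export]]
CharacterVector cpp_trim_adapter(CharacterVector reads, std::string adapter,
                                 int max_mismatch, int min_match, int search_window) {
  const int A = (int)adapter.size();
  const int n = reads.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    int L = (int)r.size();
    // leading: adapter start p in [-(A - min_match), search_window]
    int best_score = -1, best_end = -1;
    for (int p = -(A - min_match); p <= std::min(search_window, L - min_match); ++p) {
      int ov; int mm = overlap_mismatches(r, adapter, p, ov);
      if (ov < min_match || mm > max_mismatch || 4 * mm > ov) continue;
      int score = ov - mm;
      if (score > best_score) { best_score = score; best_end = p + A; }
    }
    if (best_end > 0) r = (best_end >= L) ? std::string() : r.substr((size_t)best_end);
    L = (int)r.size();
    // trailing: adapter start p in [L - A - search_window, L - min_match]
    best_score = -1; int best_start = -1;
    for (int p = std::max(0, L - A - search_window); p <= L - min_match; ++p) {
      int ov; int mm = overlap_mismatches(r, adapter, p, ov);
      if (ov < min_match || mm > max_mismatch || 4 * mm > ov) continue;
      int score = ov - mm;
      if (score > best_score) { best_score = score; best_start = p; }
    }
    if (best_start >= 0) r = r.substr(0, (size_t)best_start);
    out[i] = r;
  }
  return out;
}
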