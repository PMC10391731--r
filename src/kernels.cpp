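#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>
using namespace Rcpp;

// Semi-global unit-cost edit distance: the query is aligned end-to-end,
// gaps at either end of the reference are free (the query may align to any
// infix of the reference). Rows are pruned once every cell exceeds `cap`,
// in which case cap + 1 is returned.
static int semiglobal_core(const char* q, int m, const char* r, int n,
                           int cap) {
  if (m == 0) return 0;
  if (n == 0) return std::min(m, cap + 1);
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    int rowmin = cur[0];
    const char qc = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      int c = prev[j - 1] + (qc != r[j - 1]);
      int up = prev[j] + 1;
      if (up < c) c = up;
      int left = cur[j - 1] + 1;
      if (left < c) c = left;
      cur[j] = c;
      if (c < rowmin) rowmin = c;
    }
    if (rowmin > cap) return cap + 1;
    std::swap(prev, cur);
  }
  int best = prev[0];
  for (int j = 1; j <= n; ++j) best = std::min(best, prev[j]);
  return std::min(best, cap + 1);
}

// [[Rcpp::export]]
int edit_dist_semiglobal_cpp(std::string query, std::string ref) {
  int cap = (int)query.size() + (int)ref.size();
  return semiglobal_core(query.c_str(), query.size(), ref.c_str(), ref.size(),
                         cap);
}

// Distances from each insert to each reference, saturated at the per-insert
// cap (callers pass cap = allowed distance + margin; values above it cannot
// change the classification decision).
// [[Rcpp::export]]
IntegerMatrix dist_to_refs_cpp(CharacterVector inserts, CharacterVector refs,
                               IntegerVector caps) {
  int n = inserts.size(), k = refs.size();
  std::vector<std::string> rs(k);
  for (int j = 0; j < k; ++j) rs[j] = as<std::string>(refs[j]);
  IntegerMatrix out(n, k);
  for (int i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(inserts, i));
    int m = LENGTH(STRING_ELT(inserts, i));
    int cap = caps[i];
    for (int j = 0; j < k; ++j)
      out(i, j) = semiglobal_core(q, m, rs[j].c_str(), rs[j].size(), cap);
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Leftmost 3'-adapter match per read (cutadapt-style): at offset s the
// overlap is min(len - s, adapter length) bases of the adapter's start;
// accept if overlap >= min_overlap and mismatches <= floor(err * overlap).
// Returns the 0-based cut position, or -1 for no match.
// [[Rcpp::export]]
IntegerVector trim_adapter_cpp(CharacterVector bases, std::string adapter,
                               int min_overlap, double max_error_rate) {
  int n = bases.size(), alen = adapter.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* b = CHAR(STRING_ELT(bases, i));
    int len = LENGTH(STRING_ELT(bases, i));
    int cut = -1;
    for (int s = 0; s <= len - min_overlap; ++s) {
      int ov = std::min(len - s, alen);
      int allowed = (int)(max_error_rate * ov);
      int mm = 0;
      for (int t = 0; t < ov; ++t) {
        if (b[s + t] != adapter[t]) {
          if (++mm > allowed) break;
        }
      }
      if (mm <= allowed) { cut = s; break; }
    }
    out[i] = cut;
  }
  return out;
}

// Pass/fail of the all-bases Phred filter; counts malformed quality strings
// (any character below '!').
// [[Rcpp::export]]
List quality_filter_cpp(CharacterVector quals, int min_q,
                        double min_fraction) {
  int n = quals.size();
  LogicalVector pass(n);
  int malformed = 0;
  char thresh = (char)(min_q + 33);
  for (int i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(quals, i));
    int len = LENGTH(STRING_ELT(quals, i));
    int good = 0;
    bool bad = false;
    for (int t = 0; t < len; ++t) {
      if (q[t] < '!') { bad = true; break; }
      if (q[t] >= thresh) ++good;
    }
    if (bad) { pass[i] = false; ++malformed; continue; }
    pass[i] = (len == 0) ? false : ((double)good / len >= min_fraction);
  }
  return List::create(_["pass"] = pass, _["malformed"] = malformed);
}

// Hamming mismatches between the start of each read and `prefix`
// (prefix length if the read is shorter).
// [[Rcpp::export]]
IntegerVector prefix_mismatches_cpp(CharacterVector bases,
                                    std::string prefix) {
  int n = bases.size(), plen = prefix.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* b = CHAR(STRING_ELT(bases, i));
    int len = LENGTH(STRING_ELT(bases, i));
    if (len < plen) { out[i] = plen; continue; }
    int mm = 0;
    for (int t = 0; t < plen; ++t) mm += (b[t] != prefix[t]);
    out[i] = mm;
  }
  return out;
}

// Apply base substitutions: event e changes string idx[e] (1-based) at
// position pos[e] (1-based) by rotating the base shift[e] steps through
// ACGT, guaranteeing a different base. Non-ACGT characters are left as is.
// [[Rcpp::export]]
CharacterVector substitute_at_cpp(CharacterVector strings, IntegerVector idx,
                                  IntegerVector pos, IntegerVector shift) {
  CharacterVector out = clone(strings);
  static const char* B = "ACGT";
  int ne = idx.size();
  for (int e = 0; e < ne; ++e) {
    int i = idx[e] - 1;
    std::string s = as<std::string>(out[i]);
    int p = pos[e] - 1;
    if (p < 0 || p >= (int)s.size()) continue;
    const char* hit = strchr(B, s[p]);
    if (hit) {
      s[p] = B[(int)(hit - B + shift[e]) % 4];
      out[i] = s;
    }
  }
  return out;
}
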