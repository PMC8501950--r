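#include <Rcpp.h>
#include <string>

using namespace Rcpp;

static inline char fold(char c) {
  if (c >= 'a' && c <= 'z') return c - 32;
  return c;
}

// motif char vs sequence char: motif N matches A/C/G/T only; a sequence N
// (or any non-ACGT character) matches nothing.
static inline bool base_match(char m, char s) {
  s = fold(s);
  if (s != 'A' && s != 'C' && s != 'G' && s != 'T') return false;
  if (m == 'N') return true;
  return m == s;
}

// Greedy leftmost non-overlapping scan: on a match advance by the motif
// length, otherwise by one. Optimal for fixed-length motifs.
// [[Rcpp::export]]
int cpp_count_nonoverlap(const std::string& seq, const std::string& motif) {
  const size_t n = seq.size(), m = motif.size();
  if (m == 0 || n < m) return 0;
  int count = 0;
  size_t i = 0;
  while (i + m <= n) {
    bool hit = true;
    for (size_t j = 0; j < m; ++j) {
      if (!base_match(motif[j], seq[i + j])) { hit = false; break; }
    }
    if (hit) { ++count; i += m; } else { ++i; }
  }
  return count;
}

// Number of sequence positions that are A/C/G/T (case-folded): the
// effective (non-N) length.
// [[Rcpp::export]]
double cpp_effective_length(const std::string& seq) {
  double n = 0;
  for (char c : seq) {
    char f = fold(c);
    if (f == 'A' || f == 'C' || f == 'G' || f == 'T') ++n;
  }
  return n;
}
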