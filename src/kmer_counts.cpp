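#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Exact per-window k-mer tabulation with 2-bit rolling encoding.
// Positions whose k-mer contains any non-ACGT character are excluded from
// both the total and the distinct count (the run counter resets). With
// canonical = true each k-mer is collapsed onto the lexicographic minimum
// of itself and its reverse complement before tabulation.
// Returns c(total, distinct, singleton).
// [[Rcpp::export(name = ".kmer_window_counts")]]
NumericVector kmer_window_counts(const std::string& seq, const int k,
                                 const bool canonical = false) {
  if (k < 1) stop("k must be >= 1");
  if (k > 31) stop("k must be <= 31 for the 2-bit counter");
  NumericVector out = NumericVector::create(
    Named("total") = 0.0, Named("distinct") = 0.0, Named("singleton") = 0.0);
  const size_t n = seq.size();
  if (static_cast<size_t>(k) > n) return out;

  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  const int shift = 2 * (k - 1);
  std::vector<uint64_t> codes;
  codes.reserve(n - k + 1);

  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < n; ++i) {
    const int b = base2bits(seq[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | static_cast<uint64_t>(b)) & mask;
    rev = (rev >> 2) | (static_cast<uint64_t>(3 - b) << shift);
    if (++run >= k) {
      codes.push_back(canonical && rev < fwd ? rev : fwd);
    }
  }

  std::sort(codes.begin(), codes.end());
  const size_t total = codes.size();
  size_t distinct = 0, singleton = 0, i = 0;
  while (i < total) {
    size_t j = i + 1;
    while (j < total && codes[j] == codes[i]) ++j;
    ++distinct;
    if (j - i == 1) ++singleton;
    i = j;
  }
  out[0] = static_cast<double>(total);
  out[1] = static_cast<double>(distinct);
  out[2] = static_cast<double>(singleton);
  return out;
}
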