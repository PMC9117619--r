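#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1; // N or anything else: window is unusable
  }
}

// 2-bit rolling encoding of every k-mer starting offset. k <= 26 so the
// code fits exactly in the 52-bit mantissa of a double. Windows containing
// a non-ACGT character yield NA.
// [[Rcpp::export]]
NumericVector encode_kmers_cpp(const std::string& seq, int k) {
  const R_xlen_t L = (R_xlen_t) seq.size();
  if (k < 1 || k > 26) stop("k must be between 1 and 26");
  if (L < k) return NumericVector(0);
  const R_xlen_t nk = L - k + 1;
  NumericVector out(nk);
  const uint64_t mask = (k == 26) ? ((uint64_t(1) << 52) - 1)
                                  : ((uint64_t(1) << (2 * k)) - 1);
  uint64_t code = 0;
  R_xlen_t last_bad = -1; // most recent invalid base position
  for (R_xlen_t i = 0; i < L; ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { last_bad = i; b = 0; }
    code = ((code << 2) | (uint64_t) b) & mask;
    R_xlen_t start = i - k + 1;
    if (start >= 0) {
      out[start] = (last_bad >= start) ? NA_REAL : (double) code;
    }
  }
  return out;
}
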