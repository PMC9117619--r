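#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline char rand_base() {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  int b = (int) (unif_rand() * 4.0); if (b > 3) b = 3;
  return B[b];
}

static inline char rand_other_base(char c) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  char alt[3]; int na = 0;
  for (int i = 0; i < 4; ++i) if (B[i] != c) alt[na++] = B[i];
  int b = (int) (unif_rand() * 3.0); if (b > 2) b = 2;
  return alt[b];
}

// Indel-dominated sequencing error channel. For each reference base,
// three independent Bernoulli draws: insert a random base before it
// (prob ins), delete it (prob del), else substitute it (prob sub). The
// marginal per-reference-base rates therefore equal the nominal rates
// exactly. Emission stops once the read reaches target_len bases or the
// reference window is exhausted. Uses R's RNG, so results are
// reproducible under set.seed().
//
// Returns the read sequence, its truth CIGAR (run-length over
// {0=M,1=I,2=D}) in reference orientation, and the reference interval
// consumed (leading/trailing deletions trimmed so the CIGAR starts and
// ends with reference-and-query-consuming ops).
// [[Rcpp::export]]
List simulate_read_cpp(const std::string& ref, int start, int target_len,
                       double del, double ins, double sub) {
  std::string out; out.reserve(target_len + 16);
  std::vector<int> ops, lens;
  auto push = [&](int op, int len) {
    if (!ops.empty() && ops.back() == op) lens.back() += len;
    else { ops.push_back(op); lens.push_back(len); }
  };
  int pos = start;
  const int L = (int) ref.size();
  while ((int) out.size() < target_len && pos < L) {
    if (unif_rand() < ins) {
      out.push_back(rand_base());
      push(1, 1);
      if ((int) out.size() >= target_len) break;
    }
    if (unif_rand() < del) {
      push(2, 1);
    } else if (unif_rand() < sub) {
      out.push_back(rand_other_base(ref[pos]));
      push(0, 1);
    } else {
      out.push_back(ref[pos]);
      push(0, 1);
    }
    ++pos;
  }
  // trim leading/trailing deletion runs; shift the reference window instead
  int ref_start = start, ref_end = pos;
  if (!ops.empty() && ops.front() == 2) {
    ref_start += lens.front();
    ops.erase(ops.begin()); lens.erase(lens.begin());
  }
  if (!ops.empty() && ops.back() == 2) {
    ref_end -= lens.back();
    ops.pop_back(); lens.pop_back();
  }
  return List::create(_["seq"] = out,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()),
                      _["lens"] = IntegerVector(lens.begin(), lens.end()),
                      _["ref_start"] = ref_start, _["ref_end"] = ref_end);
}
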