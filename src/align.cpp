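#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Banded pairwise DP, global on the query, with optionally free leading
// and/or trailing gaps on the TARGET side:
//   free_start = free_end = FALSE : Needleman-Wunsch global alignment
//   free_start = free_end = TRUE  : semi-global (query floats in target)
//   free_end only                 : right boundary extension (alignment
//                                   may stop before the target's end)
//   free_start only               : left boundary extension, obtained by
//                                   the caller reversing both sequences
// Linear gap costs: every gap base costs `gap`. The band is a corridor of
// half-width `band` around the diagonals joining the two corners, wide
// enough for any length difference; the reported optimum is the
// within-band optimum.
//
// Returns ops/lens as a run-length CIGAR over {0=M, 1=I(query), 2=D(target)}
// covering target [t_start, t_start + t_used).
// [[Rcpp::export]]
List banded_align_cpp(const std::string& q, const std::string& t,
                      double match, double mismatch, double gap,
                      bool free_start, bool free_end, int band) {
  const int m = (int) q.size(), n = (int) t.size();
  if (band < 1) band = 1;
  const int shift_lo = std::min(0, n - m) - band;
  const int shift_hi = std::max(0, n - m) + band;
  const int width = shift_hi - shift_lo + 1;
  const double NEG = -1e18;

  // dir codes: 0 = origin, 1 = diag(M), 2 = up(I), 3 = left(D)
  std::vector<uint8_t> dir((size_t)(m + 1) * width, 0);
  std::vector<double> prev(width, NEG), cur(width, NEG);

  // row 0: leading target gap
  for (int j = std::max(0, shift_lo); j <= std::min(n, shift_hi); ++j) {
    int w = j - shift_lo;
    prev[w] = free_start ? 0.0 : gap * j;
    dir[w] = (j == 0 || free_start) ? 0 : 3;
  }

  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    const int off = i + shift_lo;
    const int jlo = std::max(0, off), jhi = std::min(n, i + shift_hi);
    for (int j = jlo; j <= jhi; ++j) {
      const int w = j - off;
      double best = NEG; uint8_t bd = 0;
      if (j >= 1 && w >= 0 && w < width && prev[w] > NEG) { // diag
        double s = prev[w] + (q[i - 1] == t[j - 1] ? match : mismatch);
        if (s > best) { best = s; bd = 1; }
      }
      if (w + 1 < width && prev[w + 1] > NEG) {             // up: I
        double s = prev[w + 1] + gap;
        if (s > best) { best = s; bd = 2; }
      }
      if (w - 1 >= 0 && cur[w - 1] > NEG) {                 // left: D
        double s = cur[w - 1] + gap;
        if (s > best) { best = s; bd = 3; }
      }
      cur[w] = best;
      dir[(size_t) i * width + w] = bd;
    }
    std::swap(prev, cur);
  }

  // pick the endpoint on row m
  const int off_m = m + shift_lo;
  int t_end = -1; double score = NEG;
  if (free_end) {
    for (int j = std::max(0, off_m); j <= std::min(n, m + shift_hi); ++j) {
      int w = j - off_m;
      if (prev[w] > score) { score = prev[w]; t_end = j; } // smallest j wins ties
    }
  } else {
    int w = n - off_m;
    if (w >= 0 && w < width) { score = prev[w]; t_end = n; }
  }
  if (t_end < 0 || score <= NEG)
    stop("alignment band exhausted (internal error)");

  // traceback
  std::vector<int> rops, rlens;
  int i = m, j = t_end;
  while (true) {
    uint8_t dcode = dir[(size_t) i * width + (j - (i + shift_lo))];
    if (dcode == 0) break;
    int op;
    if (dcode == 1)      { op = 0; --i; --j; }
    else if (dcode == 2) { op = 1; --i; }
    else                 { op = 2; --j; }
    if (!rops.empty() && rops.back() == op) rlens.back() += 1;
    else { rops.push_back(op); rlens.push_back(1); }
  }
  std::reverse(rops.begin(), rops.end());
  std::reverse(rlens.begin(), rlens.end());

  return List::create(_["score"] = score,
                      _["ops"] = IntegerVector(rops.begin(), rops.end()),
                      _["lens"] = IntegerVector(rlens.begin(), rlens.end()),
                      _["t_start"] = j,
                      _["t_used"] = t_end - j);
}

// Count per-base outcomes of a run-length CIGAR laid over query and target
// (target read from t_start). Used both to assemble final records and to
// recompute matched bases during evaluation.
// [[Rcpp::export]]
List cigar_stats_cpp(const std::string& q, const std::string& t,
                     IntegerVector ops, IntegerVector lens, int t_start) {
  int qi = 0, tj = t_start;
  long n_match = 0, n_mis = 0, n_ins = 0, n_del = 0;
  for (int r = 0; r < ops.size(); ++r) {
    int op = ops[r], len = lens[r];
    if (op == 0) {
      for (int x = 0; x < len; ++x) {
        if (qi >= (int) q.size() || tj >= (int) t.size())
          stop("CIGAR overruns sequence (internal error)");
        if (q[qi] == t[tj]) ++n_match; else ++n_mis;
        ++qi; ++tj;
      }
    } else if (op == 1) { n_ins += len; qi += len; }
    else if (op == 2)   { n_del += len; tj += len; }
    else stop("unknown CIGAR op code");
  }
  return List::create(_["n_match"] = (double) n_match,
                      _["n_mismatch"] = (double) n_mis,
                      _["n_ins"] = (double) n_ins,
                      _["n_del"] = (double) n_del,
                      _["q_used"] = qi, _["t_used"] = tj - t_start);
}
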