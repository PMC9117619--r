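#include <Rcpp.h>
using namespace Rcpp;

// Sparse chaining DP over the anchor neighborhood graph.
//
// Anchors must be sorted by (chrom, ref_pos, read_pos). An edge i -> j
// exists iff both anchors share a chromosome and j lies strictly forward
// of i on BOTH axes with displacement <= d. Each edge carries the constant
// reward alpha, so a vertex score counts chainable predecessors, not
// distance -- which is what lets a chain hop across a structural-variant
// gap without penalty.
//
// score(j) = max over admissible i of score(i) + alpha, else 0.
// Ties among equal-score precursors: largest ref_pos, then largest
// read_pos (the nearest one). The descending scan visits candidates in
// exactly that order, so keeping the first strict maximum implements it.
// [[Rcpp::export]]
List chain_dp_cpp(IntegerVector chrom, IntegerVector ref_pos,
                  IntegerVector read_pos, double d, double alpha) {
  const int n = chrom.size();
  NumericVector score(n);
  IntegerVector prec(n); // 1-based index of best precursor, 0 = none
  for (int j = 0; j < n; ++j) {
    double best = R_NegInf;
    int best_i = 0;
    for (int i = j - 1; i >= 0; --i) {
      if (chrom[i] != chrom[j]) break;        // sorted: chrom changes once
      double dref = (double) ref_pos[j] - ref_pos[i];
      if (dref > d) break;                    // sorted by ref_pos: done
      if (dref <= 0) continue;
      double dread = (double) read_pos[j] - read_pos[i];
      if (dread <= 0 || dread > d) continue;
      if (score[i] > best) { best = score[i]; best_i = i + 1; }
    }
    if (best_i > 0) { score[j] = best + alpha; prec[j] = best_i; }
    else            { score[j] = 0.0;          prec[j] = 0; }
  }
  return List::create(_["score"] = score, _["prec"] = prec);
}
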