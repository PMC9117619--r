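---
title: "skelmap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{skelmap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelmap)
```

## The problem

Single-molecule long reads carry 10–25% sequencing error, dominated by
insertions and deletions, and are long enough to cross structural-variant
(SV) breakpoints. Seed-and-extend mappers that penalise the distance
between seeds tend to break such reads into local fragments: the chain
stops at the SV or at an error desert, the tail is soft-clipped, and
downstream analyses lose exactly the bases that matter. `skelmap` is
organised around the opposite contract: one alignment per read, end to
end, zero clipping.

## Model and pipeline

**Anchors and the neighborhood graph.** All read k-mers (default
`k = 15`) are matched exactly against a hash index of the forward
reference strand. An anchor is a tuple (reference start, read start,
length `k`); the anchor set for a read is a bipartite match list, sorted
by reference then read position. Two anchors are joined by a directed
edge when the second lies strictly forward of the first on *both* axes
and both displacements are at most `d = floor(λ · len(read))`. Strict
forwardness makes the relation a strict partial order — the graph is a
DAG without ever being materialised; the chaining DP enumerates
admissible predecessors by a bounded backward scan over the sorted
anchors, with results identical to an explicit edge list (the
quadratic edge set is never built).

**Chaining with a constant reward.** The score recurrence
`score(v) = max(score(pred) + α)`, zero without a predecessor, uses a
constant `α = 1` per edge rather than a distance-dependent gap cost.
The chain score therefore counts anchors, not bases spanned: inserting
any gap of size ≤ d between two halves of a colinear run leaves the
score unchanged (this invariant is tested directly). That is the SV
mechanism of the whole method — the anchors flanking a deletion,
insertion, or high-error region remain one chain and the base-level
stage sees a single candidate locus.

**Refinement.** The backtracked path can pick up stray anchors caused
by repeats or chance hits far from the true locus. The refinement step
keeps the contiguous sub-path with the maximum score increase among all
sub-paths whose reference extent is below one window length
(`l = len(read)` by default). With constant rewards this is the densest
window, found by a two-pointer sweep; ties resolve to the earliest
window. The window is applied on the *reference* axis: the score gain
is a count of anchors, both axes have extent ≈ len(read), and the
reference axis is the one on which the final record's coordinates live.
Since a noisy read's true reference span is ≈ 1.01 × len(read) under
the default indel rates, the window occasionally trims a few anchors at
one end; the boundary extension below re-aligns those bases, so nothing
is lost.

**Gap classification and filling.** Consecutive skeleton anchors are
first collapsed into exact-match diagonal blocks (anchors overlapping
on one diagonal merge; an anchor overlapping the previous block across
diagonals is start-trimmed equally on both axes — the suffix of an
exact match is still an exact match — or dropped). Each inter-block gap
pair `(S_R, S_G)` is classified with threshold `μ = 2`:

* *empty* — both segments length 0;
* *deletion* — `L(S_G) > (1+μ)·L(S_R)`;
* *insertion* — `L(S_R) > (1+μ)·L(S_G)`;
* *match* — otherwise.

Match gaps are filled by global Needleman–Wunsch; deletion gaps by a
semi-global alignment of the read segment inside the reference segment
(free target ends re-emitted as D runs, so breakpoints land where the
flanking bases fit best); insertion gaps mirror this with read and
reference swapped and the overhangs re-emitted as I. Every fill
conserves both segments exactly, which is asserted at assembly time.

**Boundary extension.** The read prefix/suffix outside the outer blocks
is aligned against a reference window twice its length (clipped at the
chromosome ends) with a modified global alignment: global on the read,
free gap at the far target end only. The far-end freedom is applied
only where the method's description requires it (the unreached tail of
the window); the near end is anchored at the block. If the clipped
window is shorter than the query, surplus read bases align as I — the
record still consumes the entire read. Boundary regions are assumed
SV-free.

**Strand handling and the mapped/unmapped decision.** The reference is
indexed on the forward strand only; each read is mapped twice — as-is
and reverse-complemented — and the record with the higher alignment
score wins (ties to forward). A read is unmapped when neither strand
yields a refined skeleton of at least 2 anchors, and additionally when
the best record's total alignment score is ≤ 0: a negative-score
"alignment" is worse than reporting nothing, and the only reads that
produce one are those seeded entirely by chance k-mer collisions (a
random 2 kb read shares a chance 16-mer with a 20 kb genome a few
percent of the time). Genuine reads at even 25% error score far above
zero, so the rule only suppresses junk.

## Scoring

Two related scoring schemes appear:

* the *fill DPs* use match +1, mismatch −1, and linear −1 per gap base
  (the affine pair open = extend = −1 degenerates to this);
* the *reported alignment score* (used for strand selection and in the
  evaluation metrics) is match +1, mismatch −1, and −(length + 1) per
  maximal indel run — one open plus one extend per base; clipped bases,
  if a foreign SAM is evaluated, cost −1 without an open.

Banding: every DP runs in a corridor of half-width
`max(32, |L(query) − L(target)| + 64)` around the diagonals joining the
corners, so cost is near-linear in the gap size; the result is the
within-band optimum. For the segment sizes the skeleton produces
(anchored gaps of tens of bases; SV gaps where the band grows with the
length difference by construction) the corridor contains the
unconstrained optimum, and the suite checks the banded kernels against
a full-matrix reference DP up to 120 bp and exhaustive recursion on
tiny strings.

## The simulator

The generator stands in for an external long-read simulator and SV
benchmark so every claim is testable without downloads. It emulates:

* i.i.d. random genomes at a chosen GC content;
* SV injection — insertions of novel random sequence, deletions,
  in-place inversions — with breakpoints recorded in *original*
  reference coordinates and a mutated-to-original coordinate map, so
  reads drawn from the mutated genome can be scored against the
  original reference (the convention of SV benchmarking);
* an indel-dominated error channel: for each reference base,
  independently, insert a random base before it with probability 0.07,
  delete it with probability 0.08, else substitute it with probability
  0.01. The three draws are independent Bernoullis so the realized
  marginal rate of every channel equals its nominal rate exactly; a
  sequential "skip/don't-advance" channel would inflate the deletion
  marginal and deflate the insertion marginal by a few tenths of a
  percent, enough to fail a 3σ calibration at 10^5 bases. Higher error
  regimes rescale the three rates proportionally
  (`error_profile(total = 0.20)`).

Per read: uniform start, uniform target length in 1,000–10,000 bp
(bracketing the ~10 kb mean of current long-read datasets; reads under
1,000 bp are filtered by the mapper as is standard), uniform strand.
The truth CIGAR records the exact correspondence in reference-forward
orientation — for `-` reads it describes the reverse-complemented read,
the same orientation a SAM record uses.

What the simulator does **not** model: quality scores (the mapper is
quality-blind), homopolymer-context and burst errors, chimeric reads,
read-length distributions beyond uniform, and repeat structure beyond
what i.i.d. sequence provides. Passing tests therefore demonstrate the
algorithm's behaviour under its stated error model, not performance on
real genomes with segmental duplications or satellite repeats.

## Evaluation metrics

For simulated truth: CMR (correct chromosome and strand, truth-interval
overlap ≥ 0.9 × read length, inclusive), CMB (read base whose aligned
reference position is within T = 5 bp of its truth position; bases
inserted in either alignment carry no position and cannot count),
aligned coverage (query-consuming non-clipped CIGAR bases / read
length), sensitivity (CMB / all bases) and precision (CMB / mapped
bases), consecutiveness (share of mapped reads covered ≥ c for
c ∈ {80, 85, 90, 95}%), and breakpoint spanning (mapped interval
strictly containing the breakpoint interval). Pairwise agreement — one
alignment's outer reference interval covering ≥ 90% of another's — is
provided for cross-run comparisons; "mapped region" is the outer
interval, ignoring internal deletions.

The CMB correspondence under indels is defined by joint CIGAR walking;
an indel-displaced base is correct only if its displacement stays
within T. This is the strictest reasonable reading, and it is why
base-level sensitivity sits near ~91% at a 16% error rate while read
level recovery is ≥ 99%: inside an indel cluster the optimal alignment
legitimately places bases a few positions away from where the
generative channel put them.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on a
100 kb genome with 200 reads of 1–10 kb (both the default 8/7/1% and
the rescaled 20% error profile), plus an SV scenario with six variants
(two insertions of 300/150 bp, deletions of 500/250/100 bp, one 400 bp
inversion). These sizes exercise every stage — thousands of anchors and
hundreds of gap fills per read — while keeping a complete run in
minutes on one core. Oracle checks run the chaining DP against
exhaustive longest-path search on 200 random DAGs (≤ 12 anchors), the
three alignment kernels against a full-matrix DP on 500+ random pairs
(and exhaustive recursion on tiny strings), and the window refinement
against an O(n²) sweep on paths up to 50 anchors.

Determinism: mapping uses no randomness anywhere; ties are broken by
fixed rules (nearest equal-score precursor; smallest reference start
among maximum-score chain ends; earliest refinement window;
diagonal-preferring DP traceback; forward strand on equal scores).
Simulation is reproducible per seed. Thread count does not change
output — per-read work is independent and results are collected in
input order.

## Known limitations

* One primary alignment per read: chimeric reads and translocations are
  out of scope, as is any secondary/supplementary reporting.
* Inversions have no gap category of their own; an inversion interior
  aligns poorly (as mismatch-rich M/I/D) while the flanks chain across
  it, so breakpoint *spanning* works but the inverted bases are not
  base-correct.
* All k-mers are indexed (no minimizer sampling or homopolymer
  compression) and anchors are exact-match only; on large repetitive
  genomes the frequency mask is the only repeat defence.
* MAPQ is a constant 60 on mapped records; no mapping-quality model.
* The band contract is within-band optimality; adversarial inputs whose
  optimal path leaves the corridor would be scored suboptimally.
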