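---
title: "Detecting and profiling RNA G-quadruplexes from DMS-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and profiling RNA G-quadruplexes from DMS-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rg4scope)
```

This vignette documents the models, conventions and design choices behind
`rg4scope`: what each stage computes, which parameters matter and why they
default to what they do, what the synthetic data generator does and does not
emulate, and where the method's limits are.

## The canonical motif and the scanning policy

A canonical RNA G-quadruplex motif is four G-tracts of at least three
guanines separated by three loops of one to seven nucleotides
(G~x~N~1–7~G~x~N~1–7~G~x~N~1–7~G~x~, x ≥ 3). Three properties of a match
need a convention, because the grammar alone is ambiguous:

* **Tract extent.** Tracts are *maximal* G-runs. A run of five guanines
  contributes all five to its tract; a loop therefore never begins or ends
  with a guanine (such a guanine would extend the neighbouring tract). This
  makes the parse at a given start position unambiguous except for the
  choice of which runs serve as tracts.
* **Run choice.** Where several G-runs could serve as the next tract (for
  example five runs spaced 1–7 nt apart), the scanner takes the *nearest*
  admissible run for each subsequent tract, backtracking only when no
  completion exists. This is equivalent to choosing the lexicographically
  smallest loop-length vector and yields one deterministic parse per start.
* **Overlaps.** Matches are reported leftmost-first and non-overlapping:
  after a match, scanning resumes at its end. `scan_g4(report_overlaps =
  TRUE)` instead reports a match at every viable start, for users who want
  the full candidate set.

The quartet number of a motif is the minimum of its four tract lengths: a
(4,3,3,3)-tract motif stacks three complete quartets, and the surplus
guanine cannot add a plane on its own. Under this grammar the shortest
possible match is 4×3 + 3×1 = 15 nt, which the test suite verifies by
exhaustive scanning.

The scanner is validated against an independent brute-force enumerator that
tries every (start, tract-partition, loop-partition) tuple and applies the
same selection rule — thousands of random G-rich strings per run, with the
two implementations sharing no code.

## From RT stops to reactivity

DMS methylates accessible (unpaired) adenines and cytosines; reverse
transcription stalls one nucleotide *before* a methylated base, so a read
whose 5' end maps at position p records a stop at p − 1 (reads at position
0 are dropped — they have no upstream base). `compute_reactivity()` turns a
treated and a control stop track into per-nucleotide reactivities in four
steps, applied per transcript:

1. **Depth scaling.** Each track is divided by its own total stop count and
   multiplied by the geometric mean of the two totals, removing the
   library-size difference while keeping counts on a count-like scale.
2. **Raw signal.** At each A/C position, raw = max(0, ln(t′+1) − ln(c′+1)).
   The +1 pseudocount stabilises zeros; the zero floor discards positions
   where the control exceeds the treatment.
3. **2–8% normalization.** All raw values are divided by the mean of the
   values ranked between the 2nd and 8th percentile from the top. This
   rescales transcripts to a common unit while ignoring the most extreme
   outliers. On tracks with very few defined positions the window
   degenerates to the top value.
4. **Capping.** Values are clipped to [0, cap], cap = 7 by default.

G and T positions are undefined (`NA`): DMS chemistry does not report
them. Transcripts with zero total stops in either track, or fewer than 10
A/C positions, are skipped with a warning — a ratio of empty libraries is
meaningless, and a handful of positions cannot support the percentile
normalization.

Two numerical caveats are deliberate. The percentile window boundaries use
`floor(0.02 n)+1` through `ceiling(0.08 n)`, so the window is never empty.
And the +1 pseudocount makes reactivity only *asymptotically* invariant to
sequencing depth: doubling both libraries changes reactivities by O(1/count).
The test suite therefore checks depth-scaling invariance on deep tracks at
a small tolerance rather than exactly.

## Calling observed quadruplexes

A folded quadruplex excludes DMS from its guanine core and constrains its
loops, so reactivity inside a folded motif is depressed relative to the
rest of the transcript. The default classifier captures exactly this:

* protection score = (mean reactivity over defined A/C inside the motif) /
  (mean over all defined A/C of the transcript + ε), ε = 10⁻⁶;
* a motif is **observed** (OG4) when its score is defined and ≤ τ, with
  τ = 0.5 — "half the transcript's typical accessibility" — and
  **unfolded** (UG4) otherwise.

Motifs with no reactivity track or fewer than `min_ac` defined positions
inside (e.g. motifs whose loops are all G) cannot be probed by DMS logic at
all; they are conservatively assigned to UG4 and flagged (`no-track` /
`no-data`) rather than dropped, so the observed and unfolded sets always
partition the putative set — an invariant the tests assert on every run.
Raising τ can only grow the OG4 set (monotonicity, also tested).

Thermodynamic constrained folding is a heavier alternative to this ratio
rule. `call_og4()` therefore accepts an external engine as a plug-in
function (sequence, constraint vector, motifs → logical per motif); any
engine satisfying the contract can replace the default rule, and a failing
engine falls back to the protection score with a notice. No engine is
bundled: the package's behaviour must not depend on what is installed
around it, and the protection-ratio rule is documented, fast and
recoverable on simulated data (see below).

On synthetic data generated at a DMS-to-background signal ratio of 20 with
protection 0.1, the default classifier recovers planted folded status at a
mean balanced accuracy above 0.9 across 50 simulation seeds; the acceptance
suite re-measures this every run. The unfolded set can equivalently be
derived set-theoretically from an externally supplied observed list with
`derive_ug4()` (exact putative-minus-observed difference).

## Positional profiling

**Region assignment.** An annotation partitions each transcript into
5'-UTR [0, a), CDS [a, b), 3'-UTR [b, L). A motif is labelled by the region
containing its *start* and flagged when it spans a boundary — a single
deterministic label beats double counting, and the flag preserves the
information.

**Relative 5'-end density.** After aligning all transcripts at their 5'
ends, the density at 1-based position i is d~i~ = G~i~/T~i~ × 10³, where
G~i~ counts motifs at position i and T~i~ counts transcripts that still
have a position i. By default a motif counts at every position it covers
(occupancy), because the matching background — total motif nucleotides l
over total region length L, l/L × 10³ — is occupancy-based; `count_mode =
"start"` offers the alternative. When every transcript spans the window,
the profile mean equals the windowed background exactly (an algebraic
identity the tests check numerically). A start-codon-aligned variant scans
upstream of the CDS with the same formula.

**Metagenes.** For anchors (miRNA target-site midpoints, poly(A) sites)
and features (motif intervals), the profile at signed offset o is the
fraction of anchors whose position + o is covered by a feature, among
anchors for which that offset is still on-transcript — per-anchor
normalization, so every anchor contributes equally regardless of how many
features surround it. A control profile uses an equal number of uniform
random anchors drawn from a stated interval set (e.g. all 3'-UTRs) under a
fixed seed. Default half-windows: 100 nt for miRNA-site profiles, 200 nt
for poly(A)-site profiles, with optional 20-nt binning.

**Forming probability.** In 20-nt bins downstream of anchors, p~i~ =
d~i~/d′~i~: the occupancy density of observed motifs over that of putative
motifs, computed with identical counting rules so p~i~ ∈ [0, 1] whenever
observed ⊆ putative. Bins with zero putative density are undefined and
excluded from trend testing rather than treated as zeros.

**Trend test.** The Mann–Kendall test uses S = Σ~j>i~ sign(x~j~ − x~i~),
the tie-corrected variance [n(n−1)(2n+5) − Σ~t~ t(t−1)(2t+5)]/18, a
continuity-corrected normal deviate z = (S∓1)/√varS, and a two-sided
normal p-value. This dialect was chosen deliberately: for a tie-free series
of 10 values with S = 41 it yields p = 0.0003466 to four significant
figures, the reference behaviour the acceptance script reproduces. Constant
series return S = 0, p = 1; fewer than four values is an error.

## Expression comparisons

Transcripts are filtered at TPM strictly greater than 1 before any
expression analysis. Group comparisons use the one-sided Wilcoxon rank-sum
test (normal approximation with tie correction), alternative "group
greater".

The random-sampling procedure compares a group against repeated random
draws: each of n rounds draws, without replacement, a comparison set of
size k = min(group, pool) from the pool (subsampling the group to k when it
is the larger side) and records the one-sided p-value; the summary is the
number of rounds below 0.05. This "equal-sized random set" reading is the
only one consistent with drawing without replacement when the group
outnumbers the pool; `pseudocode_literal = TRUE` provides the variant that
draws a group-sized set from the pool *with* replacement, for users who
want that behaviour. Under the null (group drawn from the pool
distribution) the mean per-round rejection rate is calibrated at the
nominal 0.05, which the acceptance suite verifies over 100 seeded
replicates; note that rounds within one run share the same group and are
therefore correlated — the round count measures consistency of one
comparison, not independent evidence.

## The synthetic data generator

The generator exists so that every downstream stage has a ground truth.
Its defaults describe the simulated study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_transcripts` | 200 | transcriptome size |
| `utr5_len`, `cds_len`, `utr3_len` | 100–300, 300–900, 400–1200 nt | region length ranges (CDS multiples of 3); 5'-UTRs short, 3'-UTRs long, as in human mRNA |
| `gc_background` | 0.45 | background GC fraction |
| `n_g4_per_region` | 1 / 0 / 1 | planted motifs per 5'-UTR / CDS / 3'-UTR |
| `frac_folded` | 0.5 | probability a planted motif is folded |
| `lambda_bg` | 1 | Poisson background stops per position |
| `lambda_dms` | 20 | additional stops at fully accessible A/C |
| `protection` | 0.1 | accessibility multiplier inside folded motifs |
| `expr_mu`, `expr_sigma` | 3, 1 | log-normal expression (meanlog, sdlog) |
| `expr_effect` | 2 | expression multiplier for folded-3'-UTR carriers |
| `mirna_enrichment` | 0.3 | fraction of miRNA sites placed in motif windows |
| `polya_exclusion` | 50 nt | motif-free radius around poly(A) sites |

Planted motifs use tracts of three (occasionally four) guanines and loops
drawn from {A, C, T}, with non-G flanking bases, so their coordinates are
unambiguous under the maximal-tract rule. Accidental matches near planted
motifs are suppressed by rejection sampling — a transcript is resampled
until the scanner recovers the planted set exactly with no extra motif
within 30 nt — and the sequence is then re-scanned and the truth table
reconciled to the actual scan, so accidental motifs elsewhere are recorded
as unplanted, unfolded putatives instead of being silently wrong. RT stops
are independent Poisson draws: control ~ Pois(λ~bg~) everywhere; treated ~
Pois(λ~bg~ + λ~dms~·a) at A/C with a = protection inside folded motifs and
1 elsewhere, and background-only at G/T. All outputs are bit-reproducible
from (config, seed); each sub-simulation derives its own sub-seed so the
stages can be regenerated independently.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: overdispersed counts (real RT-stop data are
noisier than Poisson), coverage decay along transcripts and ligation or
priming biases, sequence-dependent RT stalling, partial or dynamic folding
(planted motifs are binary folded/unfolded with a single accessibility),
structure outside quadruplexes (the rest of the transcript is uniformly
accessible), isoform mixtures, and any coupling between expression level
and count depth. Recovery accuracies measured on this model are therefore
an upper bound on what identical settings would achieve on real libraries.

One stated generator example cannot exist under the config's own
invariants: a "no DMS signal" control (λ~dms~ = 0) violates λ~dms~ >
λ~bg~. The no-signal limit is instead verified where it is observable under
valid configs — at G/T positions, where treated minus control has mean zero.

## Problem sizes and numerical choices

The shipped tests run the scanner-versus-oracle comparison on 10,000 random
strings of length up to 40, fold-status recovery on 50 seeds of 20
transcripts each, and sampling calibration on hundreds of seeded
replicates — sizes chosen so the whole suite completes in a couple of
minutes while keeping Monte-Carlo standard errors well inside the asserted
margins. Degenerate inputs are handled explicitly rather than silently:
empty motif lists summarize to zero counts, empty anchor sets and
all-undefined forming-probability profiles are errors, skipped transcripts
warn, and invalid configurations (empty ranges, CDS not a multiple of 3,
protection ≥ 1, λ~dms~ ≤ λ~bg~) fail at construction with the violated
constraint named.

Coordinates are 0-based half-open everywhere internally and in BED output,
1-based only in human-readable profile positions; strand is always "+" in
transcript space. Reactivity files round-trip bit-exactly (values are
written with 17 significant digits).

## Known limitations

* The protection-ratio fold call is a surrogate for constrained
  thermodynamic folding; the detection threshold τ = 0.5 is a documented
  default, not a universally optimal value, and real analyses should
  examine the score distribution (`plot(fit)`) before trusting the
  partition.
* Reads are expected as per-transcript stop counts or 5'-end positions;
  alignment, trimming and quantification happen upstream.
* Motifs outside the canonical grammar (two-quartet, bulged, long-loop
  quadruplexes) are out of scope by construction.
* Genome-coordinate lifting is not provided; all analyses live in
  transcript space.
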