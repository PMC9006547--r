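---
title: "Evaluating TAD callers: models, metrics and design choices"
author: "tadbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating TAD callers: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`tadbench` evaluates topologically associating domain (TAD) calls on
binned chromatin contact matrices. Everything operates per chromosome in
0-based half-open coordinates: bp in files, bin indices internally
(`start_bin = floor(start/resolution)`, `end_bin = ceil(end/resolution)`,
snapped outward with a warning when coordinates are off the bin grid).
Four containers carry the data:

* `DomainSet` — TAD intervals, possibly nested. Any two domains must be
  disjoint or strictly nested; partial overlap is rejected at
  construction, and nesting levels are recomputed from containment rather
  than trusted from input. Minimum domain size is 2 bins: a 1-bin "domain"
  has no interior contact structure to evaluate.
* `BoundarySet` — the deduplicated, sorted union of domain start/end bins.
  A boundary shared by adjacent TADs counts once ("unique boundaries").
  By default boundaries of all nesting levels are included; a `levels`
  filter restricts to top-level domains, since whether subTAD boundaries
  count as boundaries is a genuine ambiguity for hierarchical callers.
* `ContactMatrix` — a symmetric nonnegative n×n count/frequency table.
  Matrices are accepted as already normalized; no balancing is applied.
* `PeakTrack` — regulatory-element occurrences as single bp positions.
  A BED/narrowPeak interval contributes one event at its midpoint; the
  occurrence-frequency metrics count events, not coverage.

# Boundary-element metrics

For each boundary anchored at the left edge of its bin (configurable to
the bin midpoint; the anchor convention is otherwise arbitrary):

* `A_i` — events per kb in the centred 2 kb window `[b-1000, b+1000)`.
  The window totals 2 kb, which matches the divisor of 2 in the
  average-peak definition.
* `B_i`, `C_i` — mean and sample variance of the 600 per-kb counts over
  the bilateral background `[b-500, b-200) ∪ [b+200, b+500)` kb. Sample
  variance (divisor 599) rather than population variance is used; the
  difference is negligible at 600 windows and the choice is recorded here.
* Windows running past a chromosome end are clipped: the near-window
  denominator shrinks to the covered kb, and only fully covered 1 kb
  background windows enter `B_i`/`C_i`. Clipping to the covered extent
  avoids the downward bias that zero-padding would introduce at telomeric
  boundaries.

`average_peak`, `boundary_tagged_ratio`, `fold_change` and `pvalue_ratio`
are direct functions of these statistics. Two choices deserve comment:

* **Fold-change pseudocount.** `log2(A_i/B_i)` is undefined when either
  density is zero, so both are stabilised with a pseudocount, default
  1/600 — one event spread over the full bilateral span. Note the
  consequence for sparse tracks: when the expected count in the 2 kb
  window is of order one, `A_i = 0` occurs with appreciable probability
  and the log term saturates near `log2(pc/B_i)` (≈ −8 at `B_i = 0.5`),
  so the metric's mean is dominated by the zero-window mass rather than by
  calibration. Fold change is informative for dense tracks or strong
  effects; for sparse tracks the tagged ratio and p-value ratio are the
  appropriate instruments. The package's null-calibration checks therefore
  use tracks dense enough (≈5 events/kb) that the estimator is in its
  regular regime.
* **Test sidedness.** The p-value ratio tests one-sided in a stated
  direction: upper tail for enrichment (CTCF, cohesin, TSS, ...), lower
  tail for depletion (H3K9me3-like tracks). A degenerate zero-variance
  background counts as significant iff `A_i` lies strictly on the tested
  side of `B_i`.

The element-vs-boundary "Jaccard" variants deliberately use the sum of
set sizes as denominator, not a union: boundaries and elements live on
different position scales, so a literal union is undefined. Because the
numerators count matched boundaries and matched elements separately, each
variant is bounded by 1 but their sum can exceed 1; a strict-union
variant is available behind `strict_union = TRUE`.

The enrichment profile reports per-offset densities as the mean over
boundaries of per-boundary densities (consistent with the average-peak
definition), not as pooled counts divided by pooled length — the two
disagree when boundary windows are clipped. The mean of the two central
1 kb profile bins equals the average peak, which the tests verify.

# Distance-stratified adjusted R²

At each genomic distance *d*, matrix entries `(i, i+d)` are grouped by
region and the partition is scored as
`1 − [(q−1)·SSE] / [(q−p−1)·SST]`.
The assignment rule is the substantive choice: an entry belongs to a
region only when **both** endpoints lie in the same domain (smallest
containing domain, for hierarchical calls) or the same gap run; entries
straddling a region edge are excluded from *q*. This keeps the fitted
value a genuine within-region mean. Gaps form regions with their own
means but do not contribute to *p*, which counts domains of size ≥ *d*
(all nesting levels by default, `level0_only` to restrict). The statistic
is reported as missing (not zero) when `q − p − 1 ≤ 0` or the total sum
of squares vanishes; profile summaries skip missing distances. Adding a
constant to the matrix leaves the statistic unchanged (both sums of
squares are translation-invariant), which the tests assert.

# Boundary accuracy

`match_boundaries` performs greedy one-to-one matching: truth boundaries
in ascending order each take the nearest unmatched prediction within the
tolerance, ties toward the lower bin index. Default tolerance is 0
(exact bin); recovery tests on simulations use ±1 bin to absorb the
one-bin discretisation of where "the" boundary bin of a junction lies.
One caveat is documented rather than hidden: greedy nearest-first
matching is not guaranteed symmetric in (pred, truth) when several
boundaries crowd within the tolerance; at the boundary spacings the
simulator produces (≥ 2 bins) the configurations never arise. The
quantity printed as FPR is FP/(TP+FP) — formally a false-discovery
proportion; `fdr()` is provided as an alias and the name is kept for
fidelity with the field's mixed usage.

# Corner-dot stratification

No standard definition exists for "has a corner dot", so the package
defines a deterministic, testable one: the mean contact frequency over
the `(2·halo+1)²` neighbourhood of the corner pixel `(start, end−1)`,
divided by the mean of distance-matched expected values from the
chromosome-wide decay profile. The expected model is the global
per-distance mean rather than a local donut background — cheaper, exactly
reproducible, and sufficient to separate planted loops (score ≈ δ) from
undotted domains. Defaults: halo 2, threshold 1.5. Because a TAD's corner
neighbourhood partly overlaps its own enriched block, undotted TADs score
slightly above 1 and the recovered dot fraction runs a few points above
the planted fraction at threshold 1.5; the simulation tests quantify
this (recovered ≈ 0.57 for 0.5 planted). Fractions from different
detectors are therefore not comparable bit-for-bit; within one detector
the fraction is monotone in the threshold.

# Replicate concordance

"Same TAD" means exact (start, end) bin identity — absolute concordance,
no fuzzy matching. The reproducibility level of a distinct TAD is the
number of replicates containing it. The high/low contrast groups TADs at
level > R/2 versus the rest, and pairs per replicate: each replicate
contributes the mean interaction frequency of its high-level and its
low-level TADs, compared by a one-sided Wilcoxon signed-rank test (exact
below 25 pairs, normal approximation above; ties fall back to the
approximation). Interaction frequencies are computed on whichever single
matrix is supplied — using each replicate's own matrix is equally
defensible but would entangle matrix and call variation.

# Ranking

Per metric column, the caller range [min, max] is split into four
equal-width half-open levels, ascending, with the maximum folded into
level 4. A degenerate all-equal column assigns level 1 to everyone (with
a warning) so batch runs proceed. Missing values neither rank nor fail;
the per-caller `n_ranked` column reports coverage. For depletion-type
columns a `direction = "descending"` flag flips the levels, since the
ascending rule would reward the least-depleted caller.

# The simulator

`simulate_matrix` draws Poisson counts around
`λ(i,j) = base_scale·(|i−j|+1)^−α`, multiplied by β inside planted TADs
(an extra ×1.5 inside nested subTADs) and by δ over corner
neighbourhoods of dot-labeled domains. Defaults — 500 bins at 1 kb,
α = 1, base 100, β = 3, TADs of 10–50 bins, 20% gap probability with
2–5 bin gaps, 50% dot probability at δ = 4 — are one fixed, desk-sized
emulation of a high-resolution Micro-C stretch; they are study
conditions, not tuning knobs. Noise mixes in a TAD-free background:
`round((1−ν)·M + ν·P)`, a simple, label-preserving stand-in for
read-level noise injection, monotone in ν by construction.

Two honest observations about what this emulates and what it does not:

* It captures distance decay, block enrichment, nesting, gaps, corner
  dots, and Poisson counting noise. It does not capture A/B
  compartments, mappability artefacts, balancing residuals, or genuinely
  read-level noise; passing recovery tests here shows the metrics work,
  not that any caller works on real data.
* The convex-mixing noise has a subtlety the acceptance tests expose: at
  small ν the mixture's variance shrinks quadratically
  (`(1−ν)² + ν²` times the Poisson scale) while the TAD contrast dilutes
  only linearly, so at β = 3 the insulation caller's TPR is flat to
  slightly *rising* across ν = 0.05–0.20, and the true partition's
  adjusted R² is near-constant on the same grid. The expected
  "noise hurts recovery" trend emerges only at heavy mixing (the tests
  verify a clear signal drop at ν = 0.8). This is a property of the
  noise model, left in place rather than papered over.

`simulate_peak_track` plants element tracks: homogeneous Poisson
background plus extra events near boundaries such that the near-boundary
*total* rate equals `boundary_rate` (enrichment), or thinning of
near-boundary background events to the target rate (depletion).

# Reference caller

The insulation-score caller exists to exercise the pipeline end to end:
`raw[i]` is the mean contact between the `window` bins upstream and
downstream of bin `i`; the normalized curve is `log2(raw / mean(raw))`;
boundaries are strict local minima (plateaus resolve to their leftmost
bin, deterministically), filtered by boundary strength ≥ 0.1. The
strength formula — the mean rise from the minimum to the nearest
flanking local maxima, with the valid-range end values standing in where
a side has no maximum — is this package's own reconstruction; only the
0.1 threshold is conventional. Bins within `window` of a chromosome end
have no full window, are excluded from calling, and close the outermost
domains, so a caller cannot recover boundaries at bins 0 and n: on the
default simulations this caps TPR around 0.9 before any detection error.

# Problem sizes and determinism

All stochastic checks run on 500-bin matrices with 10 seeds per battery
(5 per grid point for grids), sizes at which every property test is
stable and the full suite plus the acceptance script complete within a
few minutes on one core. Every random draw flows through an explicit
seed (`.Random.seed` is saved and restored around each draw), so
matrices, tracks, reports and the acceptance JSON are bit-reproducible
given the seed.

# Known limitations

* One chromosome per evaluation unit; multi-chromosome aggregation is an
  explicit outer loop (the CLI batches files), with unweighted means
  across chromosomes when combined.
* No matrix normalization, no .hic/.cool parsing, no re-implementation
  of published callers beyond the insulation reference, no domain-level
  (interval-overlap) accuracy — boundaries only.
* The corner-dot expected model is global; local-background (donut)
  scoring would be needed for matrices with strong compartment
  structure.
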