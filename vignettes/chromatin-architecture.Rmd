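---
title: "Methods: chromatin architecture analysis with chromarch"
author: "chromarch authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: chromatin architecture analysis with chromarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

chromarch analyses binned Hi-C contact matrices together with matched
regulatory data (peaks, signal tracks, sequences, expression counts) for
designs of the kind used in postmitotic differentiation and cohesin/CTCF
knockdown studies: a small number of paired donors per condition, deeply
sequenced contact maps, and the question of which topological features —
TAD boundaries, loops, compartments — change, and how those changes relate
to regulatory elements and transcription.

All coordinates are 0-based half-open (BED convention); 1-based inputs are
converted at the reader boundary only. Intervals that merely touch do not
overlap. A contact matrix's `total` counts the diagonal once (sum of the
upper triangle including the diagonal); depth normalisation and the
simulators use this policy consistently.

# Matrix-level statistics

**Distance expectation.** `expected_by_distance()` defines `E(d)` as the
mean count over all bin pairs at separation `d`. `obs_exp()` divides each
entry by `E(|i-j|)`; `0/0` is missing. Because `E(d)` averages the
observed matrix, the obs/exp matrix has a unit decay profile, making
expectation removal idempotent, and obs/exp is invariant under global
depth scaling.

**Compartment PC1.** The obs/exp matrix is smoothed with a small moving
average (default half-width 1 bin, i.e. a window of twice the working
resolution), its column correlation matrix is formed, and the leading
eigenvector of that symmetric matrix is the compartment track. Missing
obs/exp cells carry no compartment information and enter the correlation
as 1 (the neutral value). The eigenvector's sign is arbitrary, so it is
oriented to correlate non-negatively with a user-supplied active-chromatin
track (H3K27ac coverage or gene density); the convention is declared
rather than inherited from any tool. When the leading eigenvalue explains
less than 10% of the total variance (`min_eigen_share`) the track is
flagged unreliable — on structureless matrices the leading share is near
`1/n`, on a genuine checkerboard it is far larger, so the default
threshold separates the regimes cleanly.

**Interchromosomal maps.** Coarse (2.5-Mb) whole-genome matrices support
log2-ratio maps, `log2((A+eps)/(B+eps))` after normalising both samples to
a common total, with `eps = 1` pseudocount per normalised bin (the ratio
of a 20- vs 10-count pair is then 1.0 within a couple of percent), and
Pearson sample correlations over vectorised interchromosomal cells. What
counts as a "significant" interchromosomal interaction is not specified
beyond the original tooling; the package uses all interchromosomal cells
above a configurable pooled-count threshold (default 0) and documents this
as a stand-in.

# Domain detection

**Insulation.** `IS(i)` is the mean count over pairs `(u, v)` with `u` in
`[i-w, i-1]`, `v` in `[i+1, i+w]` — the contact flux crossing bin `i` —
reported as `log2(IS/mean IS)`; bins within `w` of an edge are missing.
**Directionality.** With `A`/`B` the summed contacts to the `w` upstream/
downstream bins and `E = (A+B)/2`,
`DI = sign(B-A) · ((A-E)^2/E + (B-E)^2/E)`; `A=B` gives 0 and `A=B=0` is
missing. Both are invariant under depth scaling (DI up to its overall
chi-square scale, which does not affect the sign changes the boundary
logic uses).

**Boundaries and TADs.** Boundaries are local insulation minima (ties
break leftmost) with prominence at least `ins_delta` that also show a DI
sign change (negative upstream, positive downstream) within ±2 bins. TADs
are the inter-boundary segments, scored as mean log2 obs/exp in the domain
triangle minus the flanking mean.

*Defaults.* The insulation/DI window is 10 bins and `ins_delta` is 1.2
log2 units. These were chosen from the contrast structure of the data the
caller is meant for, not tuned per dataset: a boundary between two domains
of enrichment `f` produces an insulation dip of about `log2 f` (1.58 at
`f = 3`), whereas an A/B compartment transition produces a genuine but
shallower dip of `2·log2 c` (0.76 at `c = 1.3`). A threshold of 1.2 sits
between the two, and the 100-kb window keeps the per-window count noise
(sd ≈ 0.1–0.2 log2 units at desk-scale depth) well below that gap. With a
narrow window or a 0.5 threshold, compartment transitions flood the
boundary list (precision ~0.25 in our recovery experiments). Both
parameters remain exposed; at the study's sequencing depth a 5-bin window
works equally well.

**Loops.** Counts are aggregated over a square window (default 3×3 bins —
the scaled analogue of calling at fine resolution while scoring a coarser
window) and tested against two expectations: the distance expectation
summed over the window, and a local expectation equal to the window
expectation scaled by the obs/exp fold of a surrounding donut annulus
(Chebyshev radius `window-1 … 2·window-1`). The donut scaling absorbs
broad elevation — domain interiors sit 2–3× above `E(d)` and would
otherwise be called wholesale. Candidates must pass fold filters
(`fold_min`, `local_fold_min`, both 2) and Poisson upper-tail tests
against both expectations after BH correction. Two multiplicity choices
matter and are deliberate:

* the BH test count is the full number of searched pixels, not the
  fold-passing candidates — candidates are selected by low p-values, so
  correcting only among them is anticonservative (measured false-discovery
  proportion 0.8 on planted data);
* the pixel-level level defaults to `alpha = 0.01` because overlapping
  windows make called pixels strongly correlated: a cluster-level (loop)
  false-discovery proportion of roughly 0.1 corresponds to a stricter
  pixel-level threshold.

The search range is 5 bins to 2 Mb (the usual focal-loop range). Adjacent
called pixels merge into one loop reported at the strongest window, ties
broken by the centre-pixel count.

**Merging and scoring.** `merge_2d()` merges features whose anchor
midpoints both lie within a tolerance, transitively and
order-independently, recording provenance. `score_features()` gives each
loop the ratio of summed contacts to summed expectation over the
anchor-pair window (anchor window default 15 kb, matching the boundary
window width; the anchor width itself is a parameter, since only the
boundary width is stated numerically in the protocols this mirrors). The
expectation is evaluated at a fixed reference scale — the normalisation
target when given — so the raw pass keeps sequencing depth in the scores
while the normalised pass removes it; raw and normalised scores then
differ per sample by exactly `total_s/target`. The custom size factors are
`SF_s = Σ raw_s / Σ norm_s`, implementing the published construction
(total scores from un-normalised scoring divided by total scores from
interaction-normalised scoring); their ratios equal the depth ratios by
design.

**Differential domains.** Raw scores are divided by `SF_s`,
log2-transformed with a pseudocount of 0.5, and tested per feature with a
Welch test against a TREAT-style shifted null for
`|logFC| > log2(fc_threshold)`; the composite p-value is
`P(T ≥ (|d|-τ)/s) + P(T ≤ -(|d|+τ)/s)`, which reduces exactly to the
ordinary two-sided Welch test at `τ = 0`. The default `fc_threshold` is 1:
the domain-score comparisons this mirrors test for any change, while the
published fold thresholds (2× between cell types, 1.5× in knockdowns)
belong to the expression/peak comparisons. The threshold matters here
because the pseudocount shrinks a true score halving (5 → 2.5) to about
0.86 log2 units; testing that against a 0.585 threshold at 3 + 3
replicates leaves too little testable effect.

# Regulatory layer

**Super-enhancers.** H3K27ac peaks whose centres lie within 2 kb of a TSS
are dropped; the rest are stitched at gaps strictly below 12 kb; stitched
enhancers get input-corrected signal floored at 0 (negative corrected
signal is not meaningful); rank and signal are scaled to the unit square;
the cutoff is where the slope of the scaled curve first reaches 1 after a
light moving-average smoothing (width 5 ranks — whether the original
tangent is computed on a smoothed curve is unstated, so the smoothing
width is a parameter). Entries above the cutoff are super-enhancers. A
curve with no sub-diagonal phase (e.g. a straight line) is flagged
degenerate and yields no calls. By construction the cutoff is invariant to
affine rescaling of the raw signal.

**Other operations.** Anchor annotation widens each anchor to a 15-kb
window centred on its midpoint and reports per-class flags and Venn-style
combination counts (anchor-level, with feature-level flags also
available). Coverage profiles conserve signal (value × overlapped bp per
bin) and flip minus-strand regions. Track scale factors equalise the mean
signal over the union of each sample's top-N peaks relative to a reference
sample and are idempotent. FRIP is the fraction of read intervals touching
any peak. Anchor-overlap enrichment builds the 2×2 membership table over a
deduplicated anchor universe and reports the sample odds ratio
(Haldane-corrected and flagged when a cell is zero) with the exact
two-sided Fisher p-value.

# Motifs

PWMs are log-odds against background frequencies (uniform 0.25 unless
supplied; pseudocount 0.01 when converting count matrices). Scanning
covers both strands; `N` scores 0. The per-peak motif score is the best
log-odds over positions and strands (a declared definition — the original
tool's score scaling is internal to it). Orientation at loop anchors uses
one representative hit per anchor — the best score, ties broken by larger
absolute score then leftmost position — and classifies loops as
convergent (`+` left, `-` right), tandem, divergent, single or none.
Motif enrichment is an upper-tail hypergeometric test per motif with BH
correction; co-association networks report the percentage of peaks
positive per class (nodes) and per class pair (edges), so every edge is
bounded by its two nodes.

# Statistical engine

Median-of-ratios factors (geometric-mean reference over features nonzero
everywhere, factors rescaled to geometric mean 1) normalise count tables;
with no all-nonzero feature the package falls back to total-count factors
with a warning. `differential_test()` works on log2-CPM with prior count
0.5 and by default moderates per-feature variances with empirical-Bayes
squeezing (the prior degrees of freedom estimated by matching the spread
of log variances to a scaled-F model). Moderation is what makes 3 + 3
designs workable: with negative-binomial dispersion 0.1 the unmoderated
Welch test at df ≈ 3 cannot reach useful sensitivity after FDR control,
while the moderated test is calibrated (null type-I error ≈ 0.045 at
α = 0.05 in our simulations) and recovers 4-fold changes with sensitivity
> 0.9. `moderate = FALSE` restores the pure Welch test, which at
`fc_threshold = 1` matches `t.test()` to machine precision.

Mann–Whitney U enumerates the permutation distribution of U over observed
mid-ranks for `n + m ≤ 20` (ties exact; two-sided p =
`P(|U - nm/2| ≥ |u - nm/2|)`) and uses the tie-corrected normal
approximation with continuity correction otherwise. Fisher's exact test
sums hypergeometric probabilities of tables no more probable than the
observed one; the odds ratio is the sample `(ad)/(bc)`.

**Ranked set enrichment.** The running sum increments by
`|stat|^p / Σ_set |stat|^p` on hits and decrements by `1/(n - set size)`
on misses; ES is the signed maximum deviation. The null comes from random
same-size sets under a fixed seed; NES divides ES by the mean |null ES| of
matching sign and the permutation p-value uses +1 smoothing
(sign-matched, like the GSEA convention). Rankings break ties by feature
id so barcode positions are deterministic. The competitive rank test — a
Wilcoxon rank-sum of set versus complement — stands in for rotation
tests; this changes calibration under inter-feature correlation, so it is
tested (and claimed) only under exchangeability. A paired design flag is
not provided at this level; donor pairing enters the pipeline through the
shared donor effects that the size factors absorb.

# The synthetic world

The generator's defaults state the world the recovery tests run in:

* genome: 2 chromosomes × 20 Mb at 10-kb bins — large enough for ≥ 25
  TADs and ≥ 50 loops, small enough for minute-scale runs;
* contact decay exponent α = 1; compartment modulation c = 1.3 in blocks
  of 50–200 bins; TAD enrichment 3 over domains that tile each chromosome
  between 25 planted internal boundaries (minimum domain 30 bins); 50
  loops with enrichment 5 spread over a 3×3 pixel neighbourhood (anchor
  fuzziness), anchor separations 100–500 kb, anchors of different loops
  kept ≥ 6 bins apart;
* conditions: a control and a knockdown-like condition in which 40% of
  loops lose 62.5% of their excess enrichment — exactly halving their
  obs/exp score (5 → 2.5);
* samples: 3 paired donors per condition; expected depth 5 × 10⁶ contacts
  per replicate (the study-scale sequencing of hundreds of millions of
  contacts on a 3-Gb genome, scaled to the 40-Mb toy genome); a shared
  log-normal donor multiplier (sd 0.1) on all of a donor's samples
  emulates the donor pairing the differential analysis exploits;
* regulatory layer: CTCF/RAD21 peaks at every loop anchor with signal
  proportional to loop enrichment (log-normal noise, sd 0.2), H3K27ac/ATAC
  at half the anchors plus 40 non-anchor enhancers, flat input; CTCF
  motif placements at anchor centres, convergent for 90% of loops; a 20-bp
  CTCF consensus written into i.i.d. background sequence;
* expression: 200 genes, baselines 50–500, NB dispersion 0.1; 20% of
  genes differential at |log2FC| = 2, half of them placed inside depleted
  loop domains (down-regulated), the rest unlinked (up); 30% flagged
  housekeeping and never differential.

Counts are multinomial draws with the total exactly equal to the requested
depth, so every generator is a pure function of its parameters and seed,
and the truth file fully determines the recovery expectations.

What the generator does **not** emulate: restriction-fragment geometry,
GC/mappability bias (the corresponding normalisation is out of scope),
read-level artefacts, nested/hierarchical TADs, and inter-feature
correlation in expression beyond the shared donor multiplier. A green
recovery test therefore establishes that the callers and the differential
machinery do what they claim on data with the stated statistical
structure — not that they reproduce any specific experimental dataset.

# Numerical conventions

Pseudocounts: 0.5 on domain scores and CPM before log2; 0.01 on PWM count
matrices; Haldane 0.5 on zero cells of 2×2 tables (flagged); +1 smoothing
on permutation p-values; eps = 1 on interchromosomal ratios. Degenerate
inputs: zero-variance features are flagged with missing p; features
overlapping > 50% zero-coverage bins are dropped from score tables and
listed; empty boundary sets yield empty (not failed) TAD calls; sets
smaller than 2 are skipped in enrichment with a warning. Ties: boundary
minima break leftmost; orientation hits break by score, then |score|,
then position; rankings break by feature id. All permutation and
simulation outputs are reproducible under a fixed seed, and the
end-to-end pipeline is bitwise reproducible per seed.

# Known limitations

The loop caller is a declared simplification (windowed focal enrichment
with donut background and Poisson/BH), benchmarked by recovery on planted
truth rather than concordance with any original tool; no matrix balancing
(ICE/KR) is applied; the competitive rank test is not a rotation test and
inherits its miscalibration under strong inter-feature correlation;
nested TADs and loop calling across chromosomes are out of scope.
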