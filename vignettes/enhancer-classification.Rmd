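---
title: "Classifying enhancers from TF binding and differential chromatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying enhancers from TF binding and differential chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerscope)
```

# The analysis in one paragraph

A lineage-determining transcription factor can shape a cell's enhancer
landscape in two directions and by two routes: it can activate or repress
an enhancer, and it can do so directly (by binding it) or indirectly
(through downstream factors). Given a knockout of the factor,
enhancerscope infers this four-way taxonomy by intersecting two
measurements at distal accessible regions: whether the factor binds the
region in wild-type cells, and whether the region's H3K27ac — the
canonical acetylation mark of active enhancers — rises or falls in the
knockout. Everything else in the package exists to make that intersection
trustworthy: replicate-consistency filtering of peak calls, a calibrated
differential test on tag counts, explicit activity and distality floors,
and motif-level evidence that the binding differences are sequence-driven.

# Data model and coordinate conventions

All intervals are 0-based, half-open, matching BED as stored on disk; BED
records round-trip unchanged through `read_bed()`/`write_bed()`. Abutting
intervals do not overlap. Peak summits are read from an optional seventh
BED column as an offset from the interval start (the narrowPeak
convention) and default to the interval midpoint. Peak-to-gene distances
are measured summit-to-TSS, ignoring strand; nearest-gene ties break to
the lexicographically smaller gene id so results are reproducible. Tag
signal is expressed as tags per 10^7 library tags throughout, the scale on
which the activity floor of 16 normalized H3K27ac tags is defined.

# Replicate reproducibility

Upstream peak callers are deliberately run permissively; the
reproducibility filter then keeps a peak only when every pairwise
replicate comparison contains a matching call. `reproducible_peaks()`
implements this as a deterministic surrogate for IDR-style filtering: a
match requires summits within `summit_dist` (default 100 bp) and both
partners within the top `rank_fraction` (default 0.9) of their replicate
by signal, checked across **all** replicate pairs (for more than two
replicates a peak must be consistent in every pair, the stricter of the
two possible readings). Surviving groups collapse to a union interval
with a signal-weighted summit and mean score. Strain-differential binding
sites — the input loci of the motif-mutation analysis — are reproducible
peaks of one strain with zero base overlap against the other strain's
reproducible set.

# The differential test

Counts in fixed windows around summits (500 bp for TF ChIP, 1,000 bp for
H3K27ac annotation of ATAC peaks) are tested per feature with a two-group
negative-binomial Wald test:

- size factors by median-of-ratios over features with all-positive
  counts;
- per-feature dispersion by method of moments on size-factor-normalized
  counts (pooled within-condition variance, with the `mean(1/s)` Poisson
  term), averaged half-and-half with a robust linear mean-dispersion
  trend `a0 + a1/mu` fitted across features (one trimming pass at 3 MAD);
- group means by NB maximum likelihood at the fixed dispersion (Newton
  iterations on the score equation), a Wald z on the log2 fold change
  with standard errors from the Fisher information, and BH adjustment
  restricted to features with baseMean of at least one normalized count
  (features below the floor report `padj = NA`).

An all-zero group is floored at half a count so the fold change stays
finite; such features carry very wide standard errors and rarely pass the
independent filter. With known dispersion the test holds its nominal
level almost exactly; with dispersion estimated from two or three
replicates the plug-in Wald test is mildly anti-conservative (null
rejection a little above 0.05 at p < 0.05), the familiar behaviour of
NB Wald tests at these sample sizes, and the test suite asserts the rate
stays within 0.05 ± 0.02 under the package's null simulation. Exact
replication of any particular DE engine is a non-goal; the contract is
calibration plus power, and an independent DESeq2 cross-check on the same
counts is part of the test suite, not the implementation.

Differential verdicts use strict thresholds: `up` means log2FC > 1 and
padj < 0.05 (log2FC exactly 1 is `unchanged`), `down` symmetric.

# Classification

Distal peaks (> 3,000 bp from the nearest TSS, strict) whose normalized
H3K27ac exceeds 16 in **at least one** condition — the same "in at least
one group" logic the expression floor uses, so an enhancer fully silenced
or fully induced by the knockout still counts as active — are classified
by the truth table bound × verdict: bound+down → direct activated,
bound+up → direct repressed, unbound+down → indirect activated,
unbound+up → indirect repressed, any verdict of unchanged → unclassified.
The partition is exhaustive and exclusive by construction. The stage
order is fixed as activity selection → differential test → TF
intersection; counts reported downstream refer to that order.

# Super-enhancers

`call_super_enhancers()` follows the ROSE recipe: peaks within 12,500 bp
stitch into regions (TSS exclusion is available but defaults to 0 since
no exclusion is part of the default contract), regions are ranked by
summed constituent signal, both axes of the ascending rank-signal curve
are scaled to [0, 1], and the cutoff is the signal at the last point
where the discrete slope is ≤ 1; regions above it are super-enhancers.
Degenerate profiles (all signals equal, or a slope never exceeding 1)
flag nothing, and fewer than three stitched regions leave the elbow
undefined (warning, all flags false). Flags are invariant to input order
and stitched signal is conserved exactly.

# Expression analyses

TPM is the length-normalized count rate scaled to 10^6 per sample; an
all-zero sample is an error, not a silent NaN. DEGs require padj < 0.05,
|FC| > 2, and group-mean log2(TPM+1) above the floor (2 by default, 4 for
stricter contrasts) in at least one of the two groups — the floor is
evaluated on group means, matching the "in at least one group" phrasing.
Signature genes compare the focal group's mean TPM against the **mean of
per-group means** of the comparison subtypes (not the pooled sample
mean), with a 0.01 TPM pseudocount in the denominator so genes silent
outside the focal type are well-defined; the threshold (default 10-fold)
is strict, making the rule monotone: a larger fold always yields a
subset. No TPM floor is applied to the focal group. Gene-set overlaps use
the hypergeometric upper tail against an explicitly supplied universe —
there is deliberately no default universe, because an unstated universe
makes enrichment p-values irreproducible.

# Motif analyses

PWM scores are log2 odds in bits with a per-cell pseudocount of 0.001
applied before the log; base 2 is forced by the match-threshold
semantics: a score of 4 means a 2^4 = 16-fold likelihood ratio over
background. Ambiguous bases contribute zero bits. Scanning reports every
window above threshold on both strands. Motif enrichment compares the
fraction of target sequences with a match against a GC-matched background
(target GC binned into deciles, background sampled per bin under a seed)
with a one-sided binomial upper tail.

Conserved-motif mapping projects matches through an alignment map
(strictly increasing aligned position pairs, from a gapped alignment or
block TSV; a global Needleman–Wunsch convenience aligner with gap open 5
and extend 2 builds maps for fixtures). A match is conserved when at
least half its positions are aligned and the homolog has a same-PWM match
within ±3 bases (a parameter, since "homologous position" tolerance is a
modelling choice) of the projected start, either strand.

The motif-mutation association takes homologous sequence pairs from a
bound and an unbound strain, computes per locus the difference in best
PWM score (max over windows and strands), drops zero differences, and
applies a two-sided Wilcoxon signed-rank test — exact by dynamic
programming over sign assignments up to n = 25 (ties handled via
midranks), normal approximation with continuity and tie corrections
beyond. Motifs with fewer than 6 informative loci are flagged
underpowered. Signed significance is `sign(median difference) ×
-log10(p)`; cluster-level values average this signed log p (rather than
signed raw p, which would let one insignificant member erase a
significant cluster) over connected components of the correlation graph
of score-difference vectors at r > 0.6 (single linkage — "maximum
correlation larger than 0.6" read as any-pair linkage). A cluster is
biologically relevant when at least one member's cognate TF exceeds
2 TPM in the focal cell type.

# What the synthetic data emulates — and what it does not

The generators produce every input the pipeline consumes, each a pure
function of a seed (bit-identical regeneration is asserted in the tests,
and the caller's RNG stream is left untouched):

- a peak universe on a grid with jitter (2 chromosomes × 10 Mb, 2,000
  peaks by default) whose TSS placement makes the distal fraction
  (default 0.8) exact by construction — distal TSSs sit at the midpoint
  of the gap to the next peak;
- planted enhancer classes (10% per class by default, with 20% of null
  peaks also TF-bound so binding alone cannot separate classes) driving
  ±2 log2 units of H3K27ac change (4-fold, the default effect size at
  which ≥95% class recovery is asserted) over NB counts with dispersion
  0.05 (ChIP-like) and log-normal feature means and library sizes;
- TF replicate calls with ≤30 bp summit jitter plus 10%
  replicate-private noise peaks, exercising the reproducibility filter;
- tag libraries that scatter each counted tag inside its counting window
  (so quantification recovers the planted counts exactly) and park
  background tags between peaks;
- an expression table with 300 signature genes (50-fold elevated in the
  focal type from a modest baseline, so the elevation does not distort
  the TPM denominator) and 400 DEGs at 4-fold, NB dispersion 0.1
  (RNA-like);
- strain pairs (200 bp, 1% background SNPs) whose negative sequences
  carry disrupting substitutions at a planted causal motif with
  probability 0.8 by default, alongside seeded Dirichlet decoy PWMs.

These defaults were chosen once as a realistic desk-scale emulation of a
sorted-cell epigenomics study and keep a full pipeline run under a few
minutes on one CPU; the vignette's and tests' problem sizes (2,000
peaks, 5,000 genes, 100 loci) are the package's stated study conditions.
What the generators do **not** emulate: mappability and copy-number
artifacts, fragment-length effects, peak-shape heterogeneity, sequence
composition beyond GC, batch structure, or correlated dispersion across
features. Passing tests therefore demonstrate the inference machinery is
correct and calibrated under its own model, not that any particular real
dataset satisfies that model.

# Numerical choices and degenerate inputs

Strict inequalities everywhere a printed threshold exists (floor 16,
fold 2, distal 3,000 bp, fold-ratio 10, PWM score 4, r 0.6). Odd
counting windows round the half-width down; windows are half-open.
Median-of-ratios requires at least one all-positive feature. The Newton
solver for group means caps steps at a ten-fold shrink per iteration and
floors empty groups at half a count. The Wilcoxon DP works on doubled
ranks so midranks stay integral. Equidistant nearest-gene ties and
identical-score ranks use deterministic tie-breaks (`ties.method =
"first"` after ordering). Peaks on chromosomes without genes are
reported as unassigned rather than dropped, and are removed (with a
warning) by the distal filter because their distance is undefined.

# Known limitations

The reproducibility filter is a deterministic stand-in with the same
contract as IDR filtering, not an estimate of an irreproducible discovery
rate. The differential engine fits no covariates and applies no fold-
change shrinkage. Peak-to-gene assignment is nearest-TSS only; chromatin-
loop-informed assignment is out of scope. The enrichment universe must be
chosen by the user, and the conserved-motif tolerance (±3 bases) is a
parameter, not an inferred quantity.
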