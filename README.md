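# enhancerscope

Regulatory-genomics tooling for dissecting how a transcription factor (TF)
shapes the enhancer landscape of a cell type, built around knockout
experiments in which the TF is removed and the chromatin response is read
out by H3K27ac ChIP-seq, ATAC-seq and RNA-seq. The motivating system is a
lineage-determining factor in microglia whose enhancer deletion (EKO)
abolishes its expression, but every step is generic.

The package is aimed at computational biologists who have peak calls, tag
counts and expression tables in hand and want the downstream inference:

- **Enhancer classification.** Active distal enhancers (normalized H3K27ac
  > 16 tags per 10^7 within ±500 bp, > 3 kb from any TSS) are partitioned
  by the joint pattern of TF binding and differential acetylation into
  four classes: *direct activated* (TF-bound, H3K27ac lost in the
  knockout), *direct repressed* (TF-bound, gained), *indirect activated*
  (unbound, lost) and *indirect repressed* (unbound, gained).
- **Differential signal.** A per-feature negative-binomial Wald test with
  median-of-ratios size factors and trend-shrunk method-of-moments
  dispersions; calls use |FC| > 2 at BH-adjusted p < 0.05.
- **Super-enhancers.** ROSE-style stitching (12.5 kb) with the tangent
  elbow on the rank-signal curve scaled to the unit square.
- **Gene programs.** TPM quantification, DEG calling with an expression
  floor on log2(TPM+1), >10-fold cell-type signature genes, and one-tailed
  hypergeometric (Fisher) gene-set overlap enrichment.
- **Motif analysis.** JASPAR PWM scanning as log2-odds bits (a score of 4
  = 16-fold likelihood over background), GC-matched motif enrichment,
  conserved-motif mapping through pairwise alignments, and a Wilcoxon
  signed-rank association between motif-disrupting strain variants and
  strain-differential TF binding, with correlation clustering of motifs
  (r > 0.6 single linkage).
- **Synthetic data.** Seeded generators plant every ground truth the
  pipeline infers — classes, fold changes, signature genes, DEGs,
  super-enhancers, causal motif mutations — so the whole analysis is
  testable without sequencing data.

## Worked example

Simulate a small study and run the full pipeline:

```r
library(enhancerscope)
b <- simulate_bundle(seed = 2, outdir = "bundle", preset = "tiny")
res <- run_pipeline(b$config)
res$summary
```

The summary printed by this run:

```
            n_peaks          n_tf_peaks            n_distal            n_active
                300                  94                 240                 240
           n_k27_up          n_k27_down  n_direct_activated  n_direct_repressed
                 46                  44                  23                  23
n_indirect_activated n_indirect_repressed     pct_up_tf_bound   pct_down_tf_bound
                 21                  23                  50                  52
            n_super            n_deg_up          n_deg_down         n_signature
                 10                  38                  45                  60
signature_down_overlap
                  1
```

Reading it: of 300 simulated ATAC peaks, 240 are distal and all 240 pass
the H3K27ac activity floor; 46 gain and 44 lose acetylation in the
knockout at |FC| > 2, padj < 0.05; combining those verdicts with the 94
reproducible TF peaks yields the four classes (23/23/21/23), close to the
~24 per class expected among distal peaks from the planted fractions. The motif stage ranks the planted
causal motif first:

```
motif    n   W    p          padj        signed_logp
CAUSAL   35  630  2.15e-07   1.93e-06    6.67
DECOY01  14  38   0.39       0.83        -0.41
```

A thin command-line wrapper with `simulate` and `run-all` subcommands is
installed at `inst/cli/enhancerscope.R`.

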