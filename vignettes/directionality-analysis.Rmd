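---
title: "Measuring transcription-initiation directionality at TSSs and intergenic accessible regions"
author: "txinit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transcription-initiation directionality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txinit)
```

## The measurement

RNA polymerase II initiation is *divergent* at most animal promoters and
enhancers: polymerase fires in both orientations from one nucleosome-depleted
region (NDR), even though productive elongation usually continues in only one.
Because H3K4 methylation, H3K27 acetylation and related marks are written
co-transcriptionally, divergent initiation leaves marks on **both** flanks of
the accessible region, while strictly unidirectional initiation — the regime
reported for flowering-plant genomes — marks only the transcribed flank.

`txinit` turns that observation into a statistic.  For each *intergenic
accessible region* (IAR — an accessible-chromatin interval outside gene
bodies, 100–2000 bp from the nearest gene), take the midpoint, build the two
2 kb windows on either side, average the signal in each (counting uncovered
bases as zero), and compare

$$x_i = \log_2(\bar s^{\text{up}}_i + 1), \qquad
  y_i = \log_2(\bar s^{\text{down}}_i + 1)$$

across the loci $i$ of a group with a two-sided Wilcoxon rank-sum test.
Loci with zero signal on *both* sides are removed first (a locus with signal
on one side only is informative and kept).  With $m$ groups tested in one
invocation, a group is called **unidirectional** when $p < \alpha/m$
(Bonferroni), with the favored side taken from the larger median;
a tested, non-significant group is called **bidirectional**.

Two deliberate choices follow the workflow this models rather than the most
powerful alternative: the test treats upstream and downstream values as two
independent samples (a rank-sum test), not as per-locus pairs — the paired
signed-rank variant is available via `wilcox.test(..., paired = TRUE)` on the
same table but is not the default — and "upstream/downstream" are genomic
(left/right of the midpoint) rather than gene-relative, matching a
midpoint±2 kb BED workflow.  Orientation relative to the nearest gene is
recorded per IAR (`relative_position`) for users who want the gene-relative
view.

## Coordinate and signal conventions

* Intervals live in `GRanges` (1-based closed) internally; BED/bedGraph
  readers and writers localize the 0-based half-open dialect.  The reported
  `midpoint` is the 0-based `floor((start0 + end0)/2)`, so an IAR spanning
  0-based `[9950, 10050)` has midpoint 10000 and flanks `[8000, 10000)` and
  `[10000, 12000)`.
* Distances between an accessible fragment and a gene are gap widths
  (bedtools-window semantics), measured from the fragment's closest edge to
  the nearest gene *boundary* by default; `anchor = "tss"` measures to the
  TSS instead.  Equidistant ties resolve to the leftmost gene by coordinate,
  making extraction order-independent.  Accessible intervals overlapping a
  gene body are clipped by per-region subtraction first; fragments narrower
  than 50 bp (configurable) are dropped.
* Region means use the `mean0` convention (uncovered bases count as zero),
  and RPKM scaling follows the binned-coverage convention
  `value × 10^9 / (bin_length × total_reads)`.
* Point-anchored profile rows for minus-strand anchors are the reversed
  values of the same genomic window, so a strand-symmetric track gives
  exactly mirrored mean profiles.  Bins outside chromosome bounds are `NA`
  and excluded from summaries.

## Metaprofiles and their uncertainty bands

`summarizeProfile()` reports, per bin, the mean, the standard error
$\mathrm{SE} = s/\sqrt n$, and a normal-approximation 95% band
$\pm 1.96\,\mathrm{SE}$; region counts in realistic uses are far above 30, so
the normal approximation is unproblematic.  When z-scoring is requested the
mean/CI curves are jointly shifted and scaled by the mean and SD of the
per-bin means (the SE is scaled only), i.e. normalization applies to the
summary curve per track, not per region — per-region scaling is available
separately.  An optional two-sided percentile trim (default 10% per tail,
applied per bin, and by the pipeline only to tracks flagged `nascent`) keeps
single high-signal loci from dominating a bin; `floor(n·f)` values are
removed per tail, so small bins are left untouched.

Scaled gene-body profiles bin the two 2 kb flanks at 50 bp and resample the
body to exactly 100 bins by averaging equal-length sub-intervals with
fractional-base weights, so genes shorter than 100 bp still produce exact
bin means.  Bin sizes are conventional metaplot defaults, not quantities
estimated from data, and are configurable.

## Clustering heatmap signal

Heatmap features are the `log2(x + 1)`-transformed, horizontally
concatenated per-track matrices (the display transform of the heatmaps; the
+1 offset keeps zeros finite), clustered with Lloyd k-means under k-means++
seeding, best of `n_init = 10` restarts by within-cluster sum of squares,
with the WCSS asserted non-increasing at every iteration.  Tracks are not
standardized by default, mirroring tools that cluster the displayed
log-scale signal; `standardizeTracks = TRUE` is available.  Clusters are
relabeled 1..k by descending size (ties by descending mean signal), since
the display order of published heatmap clusters is not itself reproducible.
`k` is a configuration value; the seed is mandatory.

Two feature-geometry options matter for interpreting clusters of
gene-*proximal* elements:

* **Window.** Within ±2 kb of an IAR that sits 100–2000 bp from a gene, the
  neighboring gene's own transcription and marks are always in view and can
  dominate the within-window variance, in which case k-means groups loci by
  gene proximity rather than by the element's own state.  The cluster stage
  therefore trims features to the element-proximal ±1 kb by default
  (`cluster$window`), where the flanking-nucleosome marks (H3K4me3 ~300 bp,
  H3K27ac ~200 bp, H2A.Z ~150 bp, H3K4me1 ~800 bp) and short eRNA signal
  live; `maskAnnotatedBins()` additionally blanks annotated-gene bins for
  users who want the full window.
* **Orientation.** A unidirectional element occurs in two mirror-image
  genomic orientations.  `orient = "dominant"` flips each row so the
  stronger half of a reference (nascent) track lies rightward — the usual
  way of pooling eRNA loci — and, because the mirror image of a genomic
  window reads the opposite strand, flipped rows swap the members of
  strand-specific track pairs (`strandPairs`).  Orientation pooling is used
  for class-recovery benchmarking (k = 3: unidirectional / bidirectional /
  inactive); the pipeline's skew grouping instead clusters *unoriented*
  features with k = 4, which separates the two unidirectional orientations
  into their own clusters — exactly what published k = 5 heatmaps show — so
  the genomic up/down rank-sum test is coherent within each cluster.

## The Wilcoxon implementation

`wilcoxonRankSum()` delegates to `stats::wilcox.test`: the exact null
distribution when the pooled sample is tie-free and $n_1+n_2 \le 25$,
otherwise the normal approximation with tie and continuity corrections.
Two samples whose pooled values are all identical return $p = 1$.  The test
suite validates the exact branch against full enumeration of all
$\binom{n_1+n_2}{n_1}$ rank splits to $10^{-12}$, and the calibration of the
full pipeline empirically: on 1000 synthetic symmetric groups
(Poisson flank totals, mean 10, $n = 100$ loci) the rejection rate at
$\alpha = 0.05$ sits inside the binomial 95% interval, and with a 4-fold
downstream shift (Poisson means 20 vs 5) every one of 200 replicate groups
is called unidirectional on the correct side.  The symmetric-null flank mean
of 10 counts is a choice of realistic magnitude — nothing in the method
depends on it — and is fixed here once.

## What the synthetic epigenome emulates

`simulateGenome()` / `simulateNascent()` / `simulatePtmTracks()` generate,
from a single seed, a compact plant-like genome and the coverage structure
the analysis assumes:

* short genes (log-normal lengths, median 1.5 kb) placed without overlap and
  with gaps of at least 7 kb — wide enough that two CREs flanking into the
  same gap can never reach each other's 1.2 kb signal neighborhoods;
* an NDR (accessibility peak, H3 dip) just upstream of every TSS;
* intergenic CREs 1200–1800 bp from a gene boundary (inside the 100–2000 bp
  IAR window, far enough that the ±1 kb clustering window is gene-free), one
  per gene-flank slot, with classes unidirectional-plus/minus, bidirectional
  and inactive; plus decoy accessible sites > 2000 bp from every gene, which
  must never survive IAR extraction;
* sense-strand nascent coverage decaying 5ʹ→3ʹ over gene bodies, short
  (~500 bp) non-elongating eRNA windows on the transcribed side(s) of CREs,
  and — for bidirectional elements — antisense initiation at
  `divergentStrength` times the sense level;
* transcription-coupled marks only on transcribed sides (H3K4me3 proximal,
  H3K4me1 distal, H3K27ac near the element, H2A.Z at the +1 nucleosome),
  H3K27me3 over inactive elements, and Poisson noise on 10 bp binned counts
  (`noise = "nb"` adds negative-binomial overdispersion, `"none"` gives the
  exact expectation).

What it does **not** emulate — and hence what passing tests cannot certify
about real data: mappability and GC artifacts, read-level processing (the
MAPQ ≥ 2 filter is assumed upstream), overlapping isoforms beyond one
interval per gene, chromatin-state autocorrelation along the genome,
distance-dependent CRE–gene coupling, and any sequence-level signal.  The
generator's role is to make the pipeline's logic falsifiable: planted
directionality classes must be recovered end to end (the acceptance script
reports the recovery rate and the adjusted Rand index of k = 3 clustering
against the planted classes), decoys must vanish, and everything must be
byte-reproducible from the seed.

## Numerical and degenerate-input policy

* Midpoints of odd-length intervals round down; flank windows clip at
  chromosome bounds with the clipping flagged.
* Empty gene sets make IAR extraction an error (the window is undefined);
  empty accessible sets return an empty annotated result.
* Groups with fewer than `minN = 10` loci after zero-filtering are reported
  as `insufficient data`, not tested, and excluded from the Bonferroni
  count `m`.
* Single-region profile matrices report `NA` SE and suppress the CI.
* k-means requires at least k rows and a seed; empty clusters during Lloyd
  iterations are re-seeded with the point farthest from its center.
* Problem sizes used in the shipped tests and acceptance script — a 2 Mb
  genome with 200 genes and 150 CREs, 1000 null groups, 200 power
  replicates — were chosen as the smallest sizes at which the binomial and
  clustering criteria are statistically meaningful.

## Known limitations

The rank-sum (unpaired) test discards the per-locus pairing and is
conservative when flank signals are strongly correlated across loci.
Bonferroni across the groups of one invocation is itself conservative when
groups are correlated.  The skew flanks deliberately include whatever the
genome puts within 2 kb — at gene-proximal elements that includes the
neighboring gene's transcription; grouping by unoriented clusters mixes the
gene's side randomly within each cluster, which keeps the group-level test
centered but adds variance.  Finally, cluster labels depend on k and the
seed in the usual k-means way; only the deterministic relabeling, not the
partition itself, is guaranteed stable across seeds.
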