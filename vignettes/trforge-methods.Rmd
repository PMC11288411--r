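---
title: "trforge: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trforge: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trforge)
```

trforge infers transcriptional-regulator (TR) activity and TR-centred gene
regulatory networks (GRNs) from single-cell RNA-seq, paired multiome and
spatial transcriptomics data.  This vignette explains the models the
package implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design choices made where the
method left the design open.  It states no empirical result that the test
suite or the acceptance script does not itself compute.

## The regulatory-potential model

A TR's genome-wide binding is summarized by its *cistrome*: a set of
ChIP-seq peaks or motif-derived pseudo-peaks.  Its influence on gene $g$ is
the regulatory potential

$$ S_g = \sum_{i=1}^{n} 2^{-d_i/d_0}, $$

where $d_i$ is the distance from the $i$-th peak centre to the TSS of $g$
and $d_0$ the half-decay distance.  TRs with more than 20% of peak centres
inside promoter windows (TSS $\pm$ 2 kb by default; the 20% rule is strict)
are *promoter-centric* and get $d_0 = 1$ kb; all others are
*enhancer-centric* with $d_0 = 10$ kb.  Peaks beyond $15\,d_0$ are skipped:
each would contribute $2^{-15} \approx 3\times10^{-5} < 5\times10^{-4}$.

The *enhanced* variant (the default for target selection) adds two rules: a
peak inside an exon of the gene contributes $1$ normalized by the gene's
total exon length, and a peak inside the promoter or an exon of another
annotated gene in range contributes $0$.  "Neighbouring genes" are all
other genes within the $15\,d_0$ window, since the method leaves the notion
unquantified.  Targets of a TR are the genes with RP $> 5$; when fewer than
300 qualify, the top 300 genes by RP are used (ties broken by gene id).

## SuperCells

Cells are pooled into *SuperCells* so that each behaves like a small
high-coverage RNA-seq sample.  Counts are normalized (counts-per-10k,
log1p), embedded by PCA (40 components by default, reduced with a warning
when there are fewer cells), joined into a Jaccard-weighted
shared-nearest-neighbour graph (10 neighbours) and clustered by Leiden at
resolution 0.8.  Within each primary cluster a secondary Leiden resolution
is binary-searched on $[0.01, 50]$ (at most 25 iterations, acceptance band
$\pm10\%$) until the mean sub-cluster size is near the target of 30 cells;
the band and bounds are termination guarantees the method does not state.
Sub-clusters under 30 cells are merged into the nearest sub-cluster by
centroid distance in PCA space; a primary cluster below 30 cells stays one
SuperCell because there is nothing to merge it into.

Markers are selected per SuperCell on the **aggregated** profiles (the
method is ambiguous here; aggregation matches its framing of a SuperCell as
an independent RNA-seq sample).  The small-dataset strategy ranks genes by
an exact one-vs-rest rank statistic and keeps the top 500; a gene must be
expressed *and positively enriched* in the SuperCell to qualify.  The
enrichment requirement is implied at full scale (top 500 of ~20 000 genes)
but has to be explicit at fixture scale, where 500 exceeds the gene count
and the ISD tests need a background disjoint from the query.  The
large-dataset strategy pools the top 1500 genes per primary cluster and
keeps candidates strictly above the SuperCell's 60th percentile
(linear-interpolation quantile).  SuperCells with fewer than 35 markers are
excluded from scoring.

## Chromatin landscapes and in-silico deletion

A chromatin profile is a 1-kb-binned genome-wide signal.  The chrom-RP of
gene $k$ in sample $j$ is

$$ RP_{jk} = \sum_{|i - t_k| \le L} w_i\, s_{ji}, \qquad L = 100\text{ kb}, $$

evaluated at bin centres.  The weight function is not printed by the
method beyond "regulatory impact of a locus"; trforge uses the same decay
family as the peak model, $w_i = 2^{-|i-t_k|/10\,\mathrm{kb}}$, following
the LISA lineage.

For RNA-only data the landscape is a panel of reference profiles; per
SuperCell, an L1-regularized logistic regression (query markers = 1,
background genes = 0; features = standardized per-sample chrom-RP) selects
up to 10 samples along a lasso path.  When the path jumps past exactly $k$
nonzero coefficients, the largest-magnitude coefficients at the first
crossing are taken.  For paired multiome data each SuperCell's own
aggregated ATAC fragments are the landscape: fragments are merged, merged
intervals are split so none exceeds 1000 bp, and coverage is binned.

*In-silico deletion* zeroes every 1-kb bin overlapping at least one peak of
the TR's cistrome and records the per-gene loss $\Delta RP \ge 0$.  Per TR
and SuperCell, one-sided Wilcoxon rank-sum tests compare query vs
background genes on each evidence channel (peak-RP, plus $\Delta RP$ per
selected sample — or the single ATAC channel when paired), and channel
P-values are combined with equal weights by the Cauchy combination test

$$ T = \tfrac1c \sum_i \tan\big((0.5 - p_i)\pi\big), \qquad
   p_{\text{summary}} = \tfrac12 - \arctan(T)/\pi, $$

clipped into $(10^{-300}, 1]$.  One background set (3000 genes by default,
capped at the annotation size) is drawn once per run and shared across
SuperCells so their summary P-values are comparable; each SuperCell's own
markers are removed from its background.  ISD work is chunked (8 chunks by
default) and chunking provably does not change results (tested).

## The activity score

With $N = -\log_{10} p_{\text{summary}}$ (base 10 is a convention choice;
the method does not print the base), the TR gene's across-SuperCell
z-score $M_{TR}$ and the mean target z-score $M_{Target}$ (each clipped
into $[-4, 4]$; constant genes get $z = 0$ to avoid NaNs) give
$M_{exp} = M_{TR} + M_{Target}$ and

$$ S = N \times \frac{M_{exp} - \min M_{exp}}{\max M_{exp} - \min M_{exp}}. $$

The min/max are global over the whole $M_{exp}$ matrix so that $S$ is
comparable across SuperCells (a per-SuperCell scope is available via
`scope = "per_supercell"`); when $M_{exp}$ is constant the factor is 0.5.
A TR with several reference datasets takes the maximum per-dataset $S$,
treating the best-matched cistrome as representative.

## Spatial embedding

For spatial data an undirected spatial neighbour network links spots within
radius $r$ (default $1.5\times$ the median nearest-neighbour spacing); a
cell-type-aware pass prunes edges whose endpoints were pre-clustered apart
(Leiden on expression PCA at resolution 0.8).  Attention over each node's
neighbours (plus self) is a softmax of scaled dot products of expression
PCA features, computed separately on the full and the pruned graph, and
combined per edge as

$$ att = (1-\alpha)\,att^{spatial} + \alpha\,att^{aware}, $$

with $\alpha = 0.5$ by default; the identity holds exactly at every
checkpoint and rows remain stochastic (tested).  The auto-encoder itself is
deliberately minimal: a linear two-layer tied-weight model on the
attention-propagated expression (hidden 64, latent 16), with PCA-informed
initialization and full-batch gradient descent whose step size grows on
success and backtracks on overshoot, so the recorded loss is non-increasing
by construction.  The cited graph-attention architecture is not restated by
the method, and a faithful minimal form keeps the embedding deterministic
and testable; the decoder output is the reconstructed normalized
expression.  SuperCells for spatial runs are clustered on the embedding
while raw counts are aggregated (the method does not say which; raw
aggregation keeps count semantics for downstream scoring).

## GRNs and ligand-receptor analysis

GRN edges connect a TR to its RP-selected targets and are kept when the
Pearson correlation of TR and target expression across SuperCells is at
least 0.3 (the method prunes "based on co-expression" without a number;
0.3 is config-exposed, and a threshold $\le -1$ keeps repressor-negative
edges).  Module structure is summarized by degree centrality on the TR-TR
shared-target projection.

Spatial crosstalk between a ligand and a receptor is the Wasserstein
distance between their expression distributions over spots (masses
normalized to unit total, Euclidean ground cost), solved exactly by a
transportation simplex with a perturbation against degeneracy; the final
plan is re-solved on the optimal basis with unperturbed masses, so
marginals hold to machine precision.  Pairs are screened by requiring a
spatial-graph neighbour of a ligand-expressing spot to express the receptor
together with a GRN TR signature (a TR whose target set contains the
receptor, with at least one target expressed there); the pooling region for
the distance is a user-supplied label, since the method does not define it.

## The synthetic world

The generator plants a fully known regulatory program: genes spaced
$\ge 30$ kb on one chromosome with 2-8 exons; per-TR peaks within 5 kb of
regulon TSSs plus 30% uniform decoys (all folds $\ge 5$); grouped
negative-binomial counts (dispersion 0.3) in which each group's active TR
targets are shifted by 2 log2 units; chromatin profiles with Poisson
background (rate 0.2) plus enrichment 5 on active peak bins, and fragments
sampled proportional to signal.  Defaults (300 genes, 900 cells, 3 groups,
3 TRs, 50-gene regulons) were chosen once so the full pipeline runs in
minutes on one CPU.

What a green test establishes: the pipeline recovers *planted* programs at
this scale under NB noise.  What it does not: realistic library-size
distributions, batch structure, dropout beyond NB sampling, genome-scale
gene density, or real cistrome/landscape panels.  One stated-world nuance:
because decoy peaks are uniform, a decoy occasionally lands beside a
non-target TSS, so "targets score higher than non-targets" holds
distributionally (all targets RP > 0, median non-target RP = 0), not
elementwise — the suite tests the distributional form.

## Numerical choices and degenerate inputs

* Motif-hit P-values come from the exact null score distribution of the
  PWM under the background model, by convolution on a 0.01-quantized score
  grid; ties in the top-N selection break by (P-value, chrom, start).
* Wilcoxon tests are exact for small tie-free samples and use the normal
  approximation with tie correction otherwise; two constant identical
  groups return $p = 1$ (no evidence), not 0.5.
* The Cauchy combination clips inputs and output into $(10^{-300}, 1]$.
* PCA sign conventions are fixed (largest-magnitude coordinate positive)
  so runs are reproducible across BLAS builds; all stochastic stages take
  seeds fanned out from one global seed.
* Degenerate cases follow the contracts: empty cistromes error in
  centricity classification, zero exon length errors in the enhanced RP,
  single SuperCells cannot be contrasted for markers, and zero-mass
  expression errors in the Wasserstein statistic.

## Known limitations

No TAD-aware weighting or enhancer-promoter loops; no cross-modal barcode
integration (pre-matched barcodes are assumed for multiome data); no
peak calling or FASTQ processing; single-cell (non-SuperCell) resolution
scoring is out of scope; the spatial module does not iterate the
cell-type-aware refinement and handles 2-D coordinates only.
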