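---
title: "Consistent DMR discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistent DMR discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`conmeth` implements a tile-based analysis of case/control bisulfite
methylation cohorts whose goal is to separate *consistent* differential
methylation — the same region, the same direction, in nearly every case
sample — from the abundant sporadic methylation changes seen in only small
sample subsets. This vignette documents the statistical models, every
tunable parameter that matters, what the synthetic cohort generator does
and does not emulate, and the design decisions taken where more than one
reasonable construction existed.

## The pipeline

1. **Tiling.** Per-CpG methylated/total read counts are pooled onto fixed,
   non-overlapping 1000 bp genomic tiles. A CpG contributes only with at
   least 10 reads in that sample; a tile is kept for a sample only with at
   least 3 contributing CpGs. These coverage filters (`tile_size = 1000`,
   `min_depth = 10`, `min_cpgs = 3`) are the standard RRBS tiling
   convention.
2. **Pairwise DMR calls.** Every case sample is compared against every
   control sample separately. Per tile, a two-sided Fisher exact test on
   the pooled 2x2 count table, with Benjamini–Hochberg FDR computed within
   each (case, control) comparison. A call requires `q < 0.01` *and* an
   absolute methylation difference of at least 25 percentage points
   (`diff_thresh = 25`, configurable down to 0). The q threshold is the
   pipeline's defining constant; the difference cutoff is the tiling
   framework's convention and is exposed because a q-value alone, at high
   coverage, flags biologically negligible differences.
3. **Common regions.** For each control batch, downstream statistics are
   restricted to tiles with a valid comparison in *every* case sample, so
   consistency counts are always out of the same denominator.
4. **Binomial consistency.** Per region and direction, the number of case
   samples called is compared with `Binomial(n_cases, p0)` using the
   one-sided upper tail; only regions called in at least `k_min = 25` of 30
   samples are tested, and BH is applied across tested regions
   (`binom_q < 0.01`). `p0` defaults to the *empirical* per-direction call
   rate over all (region, sample) cells of the batch: the test then asks
   whether a region's consistency exceeds what the genome-wide background
   call rate would produce, which is the only null that makes "consistent"
   mean "beyond background". A fixed `p0` (e.g. 0.5) can be supplied.
5. **Intersection.** A region is a C-DMR only if significant, in the same
   direction, in every control batch.
6. **Permutation validation.** Two tests, 100 permutations each, add-one
   empirical p-values `(1 + #{perm >= obs}) / (1 + n_perm)`, BH-adjusted,
   significance at `q < 0.05`:
   * *Sample permutation* — control labels are reassigned uniformly at
     random among all samples (group sizes kept), all pairwise calls are
     recomputed, and the per-region consistency count is re-derived. We
     permute labels jointly across the whole cohort, the strictest
     exchangeability null available without per-pair bookkeeping.
   * *Region permutation* — within each case sample (and each batch), the
     per-region calls are shuffled across regions, destroying regional
     structure while keeping each sample's call rate.
   The permuted statistic, in both tests, is the **minimum over control
   batches** of the per-region consistency count — the same quantity the
   C-DMR intersection thresholds. This is our construction; only the
   one-sentence description of the two tests is available as guidance.

## Methylation entropy

For region $r$ with cross-case vector $m_r = (m_{r,1}, \dots, m_{r,N})$,
$p_{s|r} = m_{r,s} / \sum_s m_{r,s}$ and
$H_r = -\sum_s p_{s|r} \log_2 p_{s|r}$ (bits; zero entries contribute 0;
$H$ is undefined when the vector sums to 0). $H_r \le \log_2 N$ with
equality iff the change is spread evenly across samples.

Two conventions exist for $m_{r,s}$: the raw methylation *level*, or the
absolute case-minus-control *difference*. Both are implemented
(`input_kind = "level"` / `"diff"`); the default is the difference, since
the quantity of interest is how methylation *change* distributes across
samples. The summary statistic reported alongside is the Pearson
correlation between $H_r$ and the absolute mean methylation change.

On the standard benchmark this correlation is negative in every control
batch (about $-0.14$, $p < 10^{-4}$). The mechanism is worth stating
because it is a property of the generative model, not an artifact: regions
changed consistently (28/30 carriers) spread their change almost uniformly
(entropy near $\log_2 30$) but so do null regions, whose residual
"changes" are exchangeable noise; sporadic focal events concentrate a
large change in 10/30 samples, which simultaneously yields a substantial
mean absolute change and a markedly reduced entropy. The negative
correlation therefore appears exactly when sporadic events are large in
magnitude relative to consistent shifts — the asymmetry the generator
encodes (below).

## The synthetic cohort generator

The generator emulates the *shape* of a small RRBS leukemia cohort — 30
case and 3 control samples — over a toy genome built from repeating
10-tile gene units (2 intergenic, 2 promoter, 5'UTR/first-exon, 3 intron,
coding-exon, 3'UTR tiles; strand alternates and the layout mirrors for
minus-strand genes). 70% of genes carry a CpG island over
TSS ± 1 kb; shores are the 2 kb island flanks; repeat and enhancer
intervals are scattered over intergenic/intron tiles; every fifth gene has
a second, shorter isoform.

Sampling model, per tile and sample: latent methylation
$\theta = \text{baseline(context)} + \text{effect} \cdot
\mathbb{1}[\text{carrier}] + \varepsilon$, clamped to $[0.01, 0.99]$;
per-CpG total reads follow a negative binomial (mean `depth = 80`,
dispersion 5) *conditioned* on at least 10 reads (inverse-CDF sampling, so
the configured mean is preserved to within a few percent and the coverage
filter boundary is exact); methylated reads are
$\text{Binomial}(\text{total}, \theta)$. Effects act on $\theta$, never on
counts, which keeps the binomial read-sampling model coherent. Truth is
recorded at tile resolution, the pipeline's unit of analysis.

Chosen conditions, fixed once:

* **Consistent regions**: ±40-point effects in 28/30 case samples —
  moderate clonal shifts. Hypermethylation is planted in CpG-island
  promoter/5'UTR tiles, hypomethylation in intron/3'UTR/intergenic tiles,
  reproducing the canonical positional split.
* **Sporadic regions**: ±70-point effects in 10/30 samples — focal,
  near-complete methylation switches confined to sample subsets, which is
  how private methylation events present in tumors (and what makes them
  low-entropy, high-magnitude outliers).
* **Noise scales**: case biological jitter sd 0.01; control heterogeneity
  sd 0.02 (`control_sd`, exposed because the controls' biological
  variability is not knowable from the study design — three donor B-cell
  populations can differ compositionally). The scales are deliberately
  small so that planted structure, not noise, dominates the benchmark;
  they still exceed read-sampling noise at the pooled tile depth.
* **Expression coupling**: per-transcript log-expression receives
  $\sum_c w_c \cdot \Delta\text{meth}_c$ with default weights
  promoter $-1$, 5'UTR $-2$, exon $-1$, intron $0$, 3'UTR $+2$, plus
  lognormal noise (sd 0.5). Signs follow the observed genic-class pattern:
  5'UTR/promoter methylation represses, 3'UTR methylation tracks
  expression positively.

What the generator does **not** emulate: read-level data (no FASTQ, no
bisulfite-conversion error), linkage between neighbouring CpGs within a
tile (all CpGs of a tile share one $\theta$), copy-number or purity
gradients, chromosome-scale covariates, and realistic inter-patient
heterogeneity of effect sizes. Tests passing on this benchmark therefore
demonstrate that the statistical machinery is correct and calibrated under
its stated model — not that real cohorts will show effects this clean.

## Annotation and expression modules

* Genic features derive from the **longest isoform** per gene
  (ties: lexicographically smallest transcript id). Promoters are
  $[\text{TSS} - 2\,\text{kb}, \text{TSS})$, strand-aware. Introns are the
  gene span minus exons. Classification uses a ≥ 1 bp overlap rule and is
  non-exclusive (percentages can exceed 100% across classes), which
  matches how multi-class region tallies are conventionally reported;
  `intergenic` means no gene-body/promoter overlap; `shore` means within
  2 kb of a CpG island (inclusive at exactly 2 kb) but outside it. The
  background set for context distributions defaults to the common-tile
  set, the universe the C-DMRs were called from.
* Interval co-localization uses a 1-df chi-square on
  [query hit/miss; rest-of-background hit/miss], falling back to Fisher's
  exact test when an expected cell drops below 1, BH across tracks.
* Metagene profiles map pooled CpG methylation onto percentile-scaled
  bodies (40 bins) with fixed 2 kb flanks (10 bins each), strand-reflected;
  boundary profiles use ±200 bp at 10 bp resolution. Bin means are the
  tested quantity; the LOESS column (tri-cube local linear, span 0.3) is
  cosmetic smoothing only. Percentile scaling is the default because
  fixed-bp scaling over genes of very different lengths mixes positions.
* Expression quartiles are rank-based with stable tie-breaking, so group
  sizes differ by at most one and the assignment is invariant under any
  strictly monotone transform.

## Correlation-module comparison

Differential matrices (each case against one common control): expression
$\log_2((\text{FPKM}+1)/(\text{FPKM}_{\text{ctrl}}+1))$ — the +1
pseudocount makes the ratio scale usable at zero FPKM — and 3'UTR
methylation difference in percentage points, restricted to transcripts
observed in both data sets.

Module detection is a deliberately simple weighted-correlation clustering:
adjacency $|r|^\beta$ with $\beta = 6$ (unsigned, so anti-correlated
variables co-cluster; a signed option exists), average-linkage
hierarchical clustering of $1 - |r|^\beta$, static cut at height 0.75,
clusters under `min_size = 30` pooled into the grey remainder, labels
ranked by size with conventional color aliases. This is a stand-in for
full weighted-network methodology (no topological overlap, no dynamic
tree cut): the comparison machinery, not the clustering flavor, is the
point, and the static cut keeps the procedure auditable.

Comparison statistics per module pair: hypergeometric upper-tail overlap
p (BH across pairs); eigengene correlation (eigengene = first right
singular vector of the per-variable z-scored module submatrix, unit norm,
sign anchored to positive mean member correlation); and permutation
preservation Z. The preservation null redraws module-sized random variable
sets (`n_perm = 100`); `Z = (obs - mean_perm)/sd_perm` for a density
statistic (mean off-diagonal test-matrix adjacency among members) and a
connectivity statistic (correlation of intramodular connectivity between
reference and test); `Z_summary` averages the non-degenerate component Zs.
When a component's permutation distribution has no numerical spread — e.g.
the connectivity statistic when reference and test matrices coincide — it
carries no information and is excluded with a warning rather than allowed
to contaminate `Z_summary` with floating-point noise. `medianRank` is the
median of the two observed statistics' cross-module ranks and involves no
permutation. The usual evidence bands apply: `Z_summary < 2` no evidence,
2–10 weak-to-moderate, > 10 strong.

## Numerical choices and degenerate inputs

* Fisher two-sided p sums hypergeometric point probabilities at most the
  observed one times $(1 + 10^{-7})$ — the standard relative guard against
  ties lost to floating point. Implemented in C++ (the permutation test
  requires all-pairs calls: ~530k exact tests on the benchmark); verified
  against exhaustive enumeration at 1e-10.
* Zero-total tiles in either sample of a pair are undefined and excluded;
  empty p-vectors return empty q-vectors; a region whose methylation
  vector sums to zero has undefined entropy and is skipped in the
  correlation.
* Duplicate CpG positions in coverage input are merged by count summation
  (with a warning); `meth_reads > total_reads` is a parse error naming the
  line.
* Constant variable rows are dropped (warning) before correlation;
  zero-variance correlation inputs yield missing results, never errors.
* All genomic intervals are 0-based half-open internally and in BED I/O.
* Determinism: one seed in `sim_config` makes every fixture byte-identical
  across runs; stage seeds are derived constants; permutation tests take
  explicit seeds.

## Problem sizes

The shipped benchmark uses 1000 tiles x 33 samples (~7000 CpGs/sample),
100 permutations for the consistency validation, 500-transcript cohorts
for the methylation-expression correlations, and 150-variable x 40-sample
matrices for the module benchmark. These sizes give every statistic a
comfortable margin over its decision threshold while keeping a full run in
the low minutes on one core; all of them scale linearly if larger studies
are simulated.

## Known limitations

* The binomial consistency test treats case samples as exchangeable and
  independent given `p0`; correlated patients (e.g. molecular subtypes)
  would need a mixed or beta-binomial model, which is out of scope.
* FDR within each pairwise comparison (rather than pooled across batches)
  follows the per-comparison testing scheme; q-values are therefore not
  comparable across batches.
* The module stand-in lacks topological-overlap smoothing, so very noisy
  blocks fragment near the cut height; the benchmark uses within-block
  correlation ~0.9, where the static cut is stable.
* With only 3 controls, the sample-permutation null has a small effective
  support (C(33,3) label assignments); empirical p-values below 1/101 are
  unreachable at the default permutation count, which is the intended
  desk-scale resolution.
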