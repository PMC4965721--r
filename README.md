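# conmeth

Tile-based discovery and characterization of **consistent differentially
methylated regions (C-DMRs)** in case/control bisulfite methylation
cohorts.

In cancer methylomes, hypermethylation tends to recur at the same
CpG-island promoters across patients, while hypomethylation is mostly
scattered — yet a subset of hypomethylated regions *is* recurrent, and
that subset is biologically informative. Separating recurrent from
sporadic methylation change in a cohort of per-CpG bisulfite counts is the
problem this package addresses. It is aimed at analysts working with
RRBS/WGBS count data (the `chrom pos meth_reads total_reads` coverage
dialect) who need a transparent, testable implementation of the whole
chain from counts to validated C-DMRs and their downstream
characterization.

## The method

For case samples $s = 1..N$ and controls $c = 1..M$, per-CpG counts are
pooled onto fixed 1000 bp tiles (≥ 3 CpGs with ≥ 10 reads each). Each
(case, control) pair is tested per tile with a two-sided Fisher exact test
on the pooled 2x2 count table; calls require BH $q < 0.01$ and
$|\Delta\text{meth}| \ge 25$ percentage points. For each control batch and
direction, a region called in $k$ of $N$ cases is scored with the
one-sided binomial tail

$$P(X \ge k), \quad X \sim \mathrm{Binomial}(N,\ p_0),$$

where $p_0$ is the empirical genome-wide per-direction call rate; regions
with $k \ge 25$ and BH $q < 0.01$ in **every** control batch are C-DMRs,
validated by two permutation tests (sample-label and region shuffles, 100
permutations, add-one empirical p, $q < 0.05$). Downstream analyses:
per-region Shannon entropy of the cross-sample methylation-change vector
$H_r = -\sum_s p_{s|r}\log_2 p_{s|r}$; genic-context annotation (promoter
= TSS−2 kb, longest isoform, ≥ 1 bp overlap); chi-square interval
co-localization; expression-quartile metagene profiles and per-class
methylation-expression Pearson correlations; and correlation-network
module comparison between differential 3'UTR methylation and differential
expression (hypergeometric overlap, eigengene correlation, permutation
preservation $Z_\text{summary}$).

A seeded synthetic-cohort generator with planted region classes (and a
tile-level truth table) makes the entire pipeline testable end to end
with no external data; see the methods vignette
(`vignettes/consistent-dmr-discovery.Rmd`) for models, parameters and
design decisions.

## Worked example

The `analysis/` directory is the narrative workflow; each numbered script
is a thin driver over package functions and writes its tables under
`results/`. Running the first four stages:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_dmr.R
Rscript analysis/03_cdmr.R
Rscript analysis/04_entropy.R
```

prints (abridged):

```
tiles: 1000 | planted:
hyper_consistent   hyper_sporadic  hypo_consistent    hypo_sporadic   null
              50               50               50               50    800

control_1: 1000 common tiles, 1900 hyper / 1900 hypo calls over 30 pairs

common regions across batches: 1000
C-DMRs: 50 hyper, 50 hypo
sensitivity on planted consistent regions: 0.990
false-call rate on sporadic+null: 0.0000

control_1: r = -0.138 (p = 1.2e-05) over 1000 regions
```

Reading this: the cohort plants 100 consistent regions (40-point effects
in 28/30 cases), 100 sporadic regions (70-point focal effects in 10/30)
and 800 null tiles. The pairwise Fisher stage calls exactly the planted
carrier effects (1900 calls per direction per batch = 50·28 + 50·10); the
binomial/intersection/permutation chain recovers 99% of the consistent
regions as C-DMRs with no false calls on sporadic or null tiles; and
region entropy is negatively correlated with the mean absolute methylation
change in every control batch — consistent large effects spread change
evenly across samples while sporadic focal events concentrate it in a few.

Stages 05–07 add genic-context distributions (hyper-C-DMRs: 100% CpG
island, 42% promoter, 58% 5'UTR; hypo-C-DMRs: 50% intron, 18% 3'UTR, 0%
island), per-class methylation-expression correlations (5'UTR
r = −0.29, 3'UTR r = +0.15 on the 100-transcript fixture) and the
module-preservation benchmark (shared planted block: overlap
q = 9.9e-41, Z_summary = 12.7, eigengene r = −1.00).

The same chain is available as a single call:

```r
library(conmeth)
run_all(run_config(out = "conmeth_run", seed = 1))
```

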