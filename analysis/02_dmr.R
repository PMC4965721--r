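#!/usr/bin/env Rscript
# Stage 2: aggregate per-CpG counts onto 1000 bp tiles (minimum 3 CpGs,
# minimum 10 reads per CpG) and call per-sample-pair DMRs against each
# control with Fisher's exact test (BH q < 0.01, |diff| >= 25 points).
library(conmeth)
library(data.table)

fx <- read_fixture("results/fixture")
cases <- grep("^case", names(fx$coverage), value = TRUE)
controls <- grep("^control", names(fx$coverage), value = TRUE)
tm <- tile_matrix(lapply(fx$coverage, aggregate_tiles))

for (ctrl in controls) {
  b <- compare_cohort(tm, cases, ctrl)
  calls <- dmr_table(b, calls_only = TRUE)
  fwrite(calls, sprintf("results/dmr_%s.tsv", ctrl), sep = "\t")
  cat(sprintf("%s: %d common tiles, %d hyper / %d hypo calls over %d pairs\n",
              ctrl, sum(b$common), sum(calls$call == "hyper"),
              sum(calls$call == "hypo"), length(cases)))
}
cat("per-pair DMR calls written to results/dmr_<control>.tsv\n")
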