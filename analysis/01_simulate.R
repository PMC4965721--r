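#!/usr/bin/env Rscript
# Stage 1: simulate the benchmark cohort and write it as a plain-text
# fixture. 30 case + 3 control samples over a 1 Mb toy genome in 1000 bp
# tiles: 50 hyper- and 50 hypo-consistent regions (40-point effects, 28/30
# carriers), 50 + 50 sporadic regions (70-point focal effects, 10/30
# carriers), 800 null tiles, and a matched expression table with
# class-specific methylation-expression coupling.
library(conmeth)

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(seed = 20160725)
coh <- simulate_cohort(cfg, dir = "results/fixture")

truth <- coh$sim$truth
cat("samples:", length(coh$sim$case_ids), "cases,",
    length(coh$sim$control_ids), "controls\n")
cat("tiles:", nrow(truth), "| planted:\n")
print(table(truth$class))
cat("CpGs per sample:", nrow(coh$sim$coverage[[1]]), "\n")
cat("fixture written to results/fixture\n")
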