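#!/usr/bin/env Rscript
# Stage 3: consistent DMRs. Binomial test on the number of case samples
# called in the same direction (>= 25 of 30, q < 0.01, empirical background
# rate), intersected across the three control batches, validated with the
# sample- and region-permutation tests (100 permutations, q < 0.05).
library(conmeth)
library(data.table)

fx <- read_fixture("results/fixture")
cases <- grep("^case", names(fx$coverage), value = TRUE)
controls <- grep("^control", names(fx$coverage), value = TRUE)
tm <- tile_matrix(lapply(fx$coverage, aggregate_tiles))
cd <- call_cdmr(tm, cases, controls, n_perm = 100L, seed = 20160725L)
fwrite(cd$results, "results/cdmr.tsv", sep = "\t")

called <- cd$results[is_cdmr == TRUE]
cat("common regions across batches:", length(cd$universe), "\n")
cat("C-DMRs:", sum(called$direction == "hyper"), "hyper,",
    sum(called$direction == "hypo"), "hypo\n")
truth <- fx$truth
cons <- truth[class %in% c("hyper_consistent", "hypo_consistent")]
hits <- mapply(function(tid, cl)
  any(called$tile_id == tid & called$direction == sub("_consistent", "", cl)),
  cons$tile_id, cons$class)
cat(sprintf("sensitivity on planted consistent regions: %.3f\n", mean(hits)))
other <- truth[!class %in% c("hyper_consistent", "hypo_consistent")]
cat(sprintf("false-call rate on sporadic+null: %.4f\n",
            mean(other$tile_id %in% called$tile_id)))
cat("results/cdmr.tsv written\n")
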