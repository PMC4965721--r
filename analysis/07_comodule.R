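#!/usr/bin/env Rscript
# Stage 7: correlation-network module comparison between differential
# expression and differential 3'UTR methylation (each case vs the first
# control), plus the planted-block benchmark of the comparison machinery.
library(conmeth)
library(data.table)

fx <- read_fixture("results/fixture")
cases <- grep("^case", names(fx$coverage), value = TRUE)
ctrl <- grep("^control", names(fx$coverage), value = TRUE)[1]
feats <- gene_features(fx$genes)
dm <- build_differential_matrices(fx$expression, fx$coverage, feats,
                                  cases, ctrl)
cat("differential matrices over", nrow(dm$expr), "transcripts x",
    ncol(dm$expr), "case samples\n")
# the small fixture rarely yields stable modules at the conventional
# minimum size; report what the data give
mse <- detect_modules(dm$expr, min_size = min(30L, nrow(dm$expr) %/% 4L))
msm <- detect_modules(dm$meth, min_size = min(30L, nrow(dm$meth) %/% 4L))
cat("expression modules:", length(mse$modules),
    "| methylation modules:", length(msm$modules), "\n")
fwrite(mse$membership, "results/comodule_membership_expr.tsv", sep = "\t")
fwrite(msm$membership, "results/comodule_membership_meth.tsv", sep = "\t")
if (length(mse$modules) && length(msm$modules)) {
  ct <- crosstab_overlap(msm, mse, rownames(dm$expr))
  fwrite(ct, "results/comodule_overlap.tsv", sep = "\t")
  pz <- preservation_z(mse, dm$expr, dm$meth, n_perm = 100L, seed = 1L)
  fwrite(pz, "results/comodule_preservation.tsv", sep = "\t")
  ec <- eigengene_correlation(msm, mse)
  fwrite(ec, "results/comodule_eigengene_cor.tsv", sep = "\t")
}

# planted shared-factor benchmark: one block shared (sign -1) between the
# two matrices, one private, 50 background variables
bm <- simulate_block_matrices(n_var = 150L, n_samples = 40L,
                              blocks = list(
                                list(vars = 1:50, shared = TRUE, sign = -1),
                                list(vars = 51:100, shared = FALSE,
                                     sign = 1)),
                              noise_sd = 1 / 3, seed = 99L)
msa <- detect_modules(bm$a, min_size = 30L)
msb <- detect_modules(bm$b, min_size = 30L)
sh <- as.character(msa$membership[variable_id == "var_001"]$module)
ct <- crosstab_overlap(msa, msb, rownames(bm$a))
pz <- preservation_z(msa, bm$a, bm$b, n_perm = 100L, seed = 2L)
ec <- eigengene_correlation(msa, msb)
shb <- as.character(msb$membership[variable_id == "var_001"]$module)
cat(sprintf("benchmark shared block: overlap q = %.2g, Z_summary = %.1f, eigengene r = %.2f\n",
            ct[module_a == sh & module_b == shb]$fisher_q,
            pz[module == sh]$Z_summary,
            ec[module_a == sh & module_b == shb]$r))
fwrite(pz, "results/comodule_benchmark_preservation.tsv", sep = "\t")
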