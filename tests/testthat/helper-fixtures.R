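# Shared simulated fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the standard benchmark cohort: 1000 tiles, 30 cases + 3 controls,
# 50 + 50 consistent, 50 + 50 sporadic, 800 null tiles
std_cohort <- function() cached("std_cohort", simulate_cohort(sim_config(seed = 20160725)))

std_tile_matrix <- function() cached("std_tm", {
  tile_matrix(lapply(std_cohort()$sim$coverage, aggregate_tiles))
})

# full C-DMR calling incl. the two permutation tests
std_cdmr <- function() cached("std_cdmr", {
  coh <- std_cohort()
  call_cdmr(std_tile_matrix(), coh$sim$case_ids, coh$sim$control_ids,
            n_perm = 100L, seed = 42L)
})

# tiny deterministic gene-model table: two genes on opposite strands,
# gene_b with two isoforms
toy_models <- function() {
  data.table::data.table(
    transcript_id = c("txA1", "txB1", "txB2"),
    gene_id = c("gene_a", "gene_b", "gene_b"),
    chrom = c("chr1", "chr1", "chr1"),
    strand = c("+", "-", "-"),
    txStart = c(10000, 30000, 32000),
    txEnd = c(16000, 38000, 38000),
    cdsStart = c(10400, 30800, 32400),
    cdsEnd = c(15200, 37600, 37600),
    exonStarts = c("10000,14000", "30000,37000", "32000"),
    exonEnds = c("11000,16000", "32000,38000", "38000"))
}
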