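test_that("promoter intervals follow the -2 kb..TSS definition, strand-aware", {
  feats <- gene_features(toy_models())
  plus <- feats$promoter[feats$promoter$gene_id == "gene_a"]
  expect_equal(c(plus$start, plus$end), c(8000, 10000))
  minus <- feats$promoter[feats$promoter$gene_id == "gene_b"]
  expect_equal(c(minus$start, minus$end), c(38000, 40000))
})

test_that("annotation and fixture output are byte-identical across runs", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 1e5,
                    planted = list(list(class = "hypo_consistent", n = 2L,
                                        effect = -40, carrier_fraction = 28 / 30,
                                        context = "intron")),
                    seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(cfg, dir = d1)
  simulate_cohort(cfg, dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
})

test_that("tile contexts in the truth table match the layout", {
  ann <- build_genome_annotation(sim_config(n_chroms = 1,
                                            chrom_length = 1e5, seed = 3))
  # every genic class is represented
  expect_true(all(c("promoter", "utr5", "exon", "intron", "utr3",
                    "intergenic") %in% ann$tiles$context))
  # intron tiles of a plus-strand gene lie strictly inside the gene span
  g1 <- ann$genes[ann$genes$transcript_id == "tx_0001_1"]
  itiles <- ann$tiles[gene_id == "gene_0001" & context == "intron"]
  expect_true(all(itiles$start >= g1$txStart & itiles$end <= g1$txEnd))
  # tile boundaries are 0-based half-open multiples of the tile size
  expect_true(all(ann$tiles$start %% 1000 == 0))
  expect_equal(ann$tiles$end - ann$tiles$start, rep(1000, nrow(ann$tiles)))
})

test_that("empty genic classes raise a configuration error naming the class", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 1e5, seed = 1,
                    island_fraction = 0)
  expect_error(build_genome_annotation(cfg), "cpg_island")
})

test_that("read depth matches the truncated negative-binomial model", {
  cfg <- sim_config(seed = 11, depth = 50)  # 1000 tiles x ~7 CpGs per sample
  coh <- simulate_cohort(cfg)
  cov1 <- coh$sim$coverage[[1]]
  expect_gt(nrow(cov1), 5000)
  expect_true(all(cov1$total_reads >= 10))
  # law of large numbers: empirical mean within 5% of the configured depth
  expect_lt(abs(mean(cov1$total_reads) - 50) / 50, 0.05)
})

test_that("planted carriers are drawn exactly and effects are recoverable", {
  coh <- std_cohort()
  truth <- coh$sim$truth
  cons <- truth[class == "hypo_consistent"]
  expect_true(all(cons$n_carriers == 28L))
  expect_true(all(vapply(strsplit(cons$carriers, ","), length,
                         integer(1)) == 28L))
  # mean observed tile delta among carriers within +-5 points of the effect
  tm <- std_tile_matrix()
  lv <- tm$level
  ctrl_mean <- rowMeans(lv[, coh$sim$control_ids, drop = FALSE])
  deltas <- vapply(seq_len(nrow(cons)), function(i) {
    carriers <- strsplit(cons$carriers[i], ",")[[1]]
    ri <- match(cons$tile_id[i], tm$regions$tile_id)
    mean(100 * (lv[ri, carriers] - ctrl_mean[ri]))
  }, numeric(1))
  expect_lt(abs(mean(deltas) - (-40)), 5)
})

test_that("null cohort tiles deviate from baseline only by sampling noise", {
  cfg <- sim_config(n_chroms = 1, planted = NULL, seed = 21)
  coh <- simulate_cohort(cfg)
  tm <- tile_matrix(lapply(coh$sim$coverage, aggregate_tiles))
  dif <- rowMeans(tm$level[, coh$sim$case_ids]) -
    rowMeans(tm$level[, coh$sim$control_ids, drop = FALSE])
  se <- sd(dif) / sqrt(length(dif))
  expect_lt(abs(mean(dif)), 3 * se)
})

test_that("out-of-range baseline + effect is clamped with a warning", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 5e4,
                    planted = list(list(class = "hypo_consistent", n = 2L,
                                        effect = -90, carrier_fraction = 1,
                                        context = "utr5")),
                    seed = 5)
  ann <- build_genome_annotation(cfg)
  expect_warning(simulate_methylation(cfg, ann), "clamp")
})

test_that("expression couples to methylation with the configured signs", {
  # all-zero coupling: expression independent of methylation (>= 200
  # transcripts so the null correlation band is tight)
  cfg0 <- sim_config(seed = 31, n_chroms = 4,
                     coupling = c(utr5 = 0, utr3 = 0))
  coh0 <- simulate_cohort(cfg0)
  truth <- coh0$sim$truth
  base <- ifelse(truth$in_island, 0.15,
                 cfg0$baseline_meth[truth$context])
  dmeth_utr5 <- vapply(rownames(coh0$expression), function(tx) {
    gid <- coh0$annotation$genes[transcript_id == tx]$gene_id
    rows <- which(truth$gene_id == gid & truth$context == "utr5")
    mean(coh0$sim$theta[rows, coh0$sim$case_ids] - base[rows])
  }, numeric(1))
  expr_mean <- rowMeans(log(coh0$expression[, coh0$sim$case_ids]))
  expect_lt(abs(cor(dmeth_utr5, expr_mean)), 0.1)

  # negative 5'UTR coupling: negative correlation, p < 0.01
  coh <- std_cohort()  # default coupling: utr5 -2
  truth <- coh$sim$truth
  base <- ifelse(truth$in_island, 0.15, cfg0$baseline_meth[truth$context])
  d5 <- vapply(rownames(coh$expression), function(tx) {
    gid <- coh$annotation$genes[transcript_id == tx]$gene_id
    rows <- which(truth$gene_id == gid & truth$context == "utr5")
    mean(coh$sim$theta[rows, coh$sim$case_ids] - base[rows])
  }, numeric(1))
  ct <- cor.test(d5, rowMeans(log(coh$expression[, coh$sim$case_ids])))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("fixtures round-trip losslessly through the package readers", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 1e5, planted = NULL,
                    seed = 13)
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(cfg, dir = dir)
  fx <- read_fixture(dir)
  s1 <- names(coh$sim$coverage)[1]
  expect_equal(as.data.frame(fx$coverage[[s1]]),
               as.data.frame(coh$sim$coverage[[s1]]))
  expect_equal(unname(fx$expression), unname(coh$expression),
               tolerance = 1e-12)
  expect_equal(nrow(fx$truth), nrow(coh$annotation$tiles))
  # BED serialization is 0-based half-open
  bed <- readLines(file.path(dir, "cpg_island.bed"), n = 1)
  isl <- coh$annotation$tracks$cpg_island[1]
  expect_identical(bed, paste(isl$chrom, isl$start, isl$end, sep = "\t"))
  # invalid planted configuration is rejected
  expect_error(sim_config(planted = list(list(class = "hypo_consistent",
                                              n = 1L, effect = -40,
                                              carrier_fraction = 0.5,
                                              context = "intron"))),
               "carrier_fraction")
  blocker <- withr::local_tempfile(lines = "x")  # a plain file, not a dir
  expect_error(
    suppressWarnings(write_fixture(coh, file.path(blocker, "sub"))), "writ")
})
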