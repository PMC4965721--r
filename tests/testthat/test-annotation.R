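test_that("reference isoform selection picks the longest, ties by id", {
  models <- toy_models()
  ref <- select_reference_isoform(models)
  expect_equal(nrow(ref), 2L)
  expect_equal(ref[gene_id == "gene_b"]$transcript_id, "txB1")  # 8 kb > 6 kb
  one <- select_reference_isoform(models[transcript_id == "txA1"])
  expect_equal(one$transcript_id, "txA1")
  tie <- data.table::data.table(
    transcript_id = c("txB", "txA"), gene_id = "g", chrom = "chr1",
    strand = "+", txStart = 0, txEnd = 5000, cdsStart = 100, cdsEnd = 4900,
    exonStarts = "0", exonEnds = "5000")
  expect_equal(select_reference_isoform(tie)$transcript_id, "txA")
})

test_that("gene features are derived strand-aware from the reference
           isoform", {
  feats <- gene_features(toy_models())
  a <- function(cls, gid) as.data.frame(
    feats[[cls]][feats[[cls]]$gene_id == gid, c("start", "end")])
  expect_equal(a("utr5", "gene_a"), data.frame(start = 10000, end = 10400))
  expect_equal(a("utr3", "gene_a"), data.frame(start = 15200, end = 16000))
  expect_equal(a("intron", "gene_a"), data.frame(start = 11000, end = 14000))
  # minus strand gene: 5'UTR at the high-coordinate end
  expect_equal(a("utr5", "gene_b"), data.frame(start = 37600, end = 38000))
  expect_equal(a("utr3", "gene_b"), data.frame(start = 30000, end = 30800))
})

test_that("strand reversal reflects the promoter about the gene body", {
  m <- toy_models()[transcript_id == "txA1"]
  fwd <- gene_features(m)$promoter
  m$strand <- "-"
  rev <- gene_features(m)$promoter
  expect_equal(c(fwd$start, fwd$end), c(8000, 10000))
  expect_equal(c(rev$start, rev$end), c(16000, 18000))
})

test_that("region classification follows the 1 bp overlap and boundary
           rules", {
  feats <- gene_features(toy_models())
  feats$cpg_island <- data.table::data.table(chrom = "chr1", start = 6000,
                                             end = 8000)
  regions <- data.table::data.table(
    chrom = "chr1",
    start = c(8500, 11500, 10000, 50000, 9999),
    end = c(9500, 12500, 11000, 51000, 10001))
  cls <- classify_region(regions, feats)
  expect_true(cls[1, "promoter"])       # [8500,9500) in [8000,10000)
  expect_false(cls[1, "gene_body"])
  expect_true(cls[2, "intron"])         # inside gene, intron only
  expect_false(cls[2, "exon"])
  expect_false(cls[2, "intergenic"])
  expect_true(cls[4, "intergenic"])     # far from any gene
  expect_true(cls[5, "promoter"] && cls[5, "exon"])  # 1 bp on each side
  # shore boundary: gap of exactly 2000 bp still counts
  expect_true(cls[3, "shore"])          # [10000,11000) vs island end 8000
  expect_true(cls[1, "shore"])          # gap 500 below the island -> shore
  expect_false(cls[4, "shore"])         # 42 kb away
  expect_error(classify_region(
    data.table::data.table(chrom = "chrZ", start = 1, end = 2), feats),
    "chrZ")
})

test_that("location distribution equals hand counts on a toy set", {
  feats <- gene_features(toy_models())
  q <- data.table::data.table(chrom = "chr1",
                              start = c(8500, 11500, 50000, 15200),
                              end = c(9500, 12500, 51000, 15300))
  bg <- data.table::data.table(chrom = "chr1", start = (0:9) * 5000,
                               end = (0:9) * 5000 + 1000)
  ld <- location_distribution(q, bg, feats)
  expect_equal(ld[ld$class == "promoter"]$query_frac, 1 / 4)
  expect_equal(ld[ld$class == "intron"]$query_frac, 1 / 4)
  expect_equal(ld[ld$class == "utr3"]$query_frac, 1 / 4)
  expect_equal(ld[ld$class == "intergenic"]$query_frac, 1 / 4)
  # bg tiles: [10000,11000) exon/utr5; [15000,16000) exon/utr3;
  # [30000,31000) + [35000,36000) in gene_b; promoter [5000,6000)? no:
  # promoters are [8000,10000) and [38000,40000) -> 0 bg promoter hits
  expect_equal(ld[ld$class == "promoter"]$background_frac, 0)
  expect_equal(ld[ld$class == "exon"]$background_frac, 0.3)
  identical_rows <- location_distribution(q, q, feats)
  expect_equal(identical_rows$query_frac, identical_rows$background_frac)
  expect_error(location_distribution(q[0], bg, feats), "empty")
})

test_that("classification agrees with a naive all-pairs scan on random
           regions", {
  set.seed(8)
  ann <- build_genome_annotation(sim_config(seed = 8))
  feats <- gene_features(ann$genes)
  feats$cpg_island <- ann$tracks$cpg_island
  feats$`repeat` <- ann$tracks$`repeat`
  n <- 1000
  regions <- data.table::data.table(
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    start = sample.int(499000, n))
  regions[, end := start + sample.int(3000, n)]
  cls <- classify_region(regions, feats)
  for (cc in c("promoter", "utr5", "exon", "intron", "utr3", "cpg_island",
               "repeat"))
    expect_equal(unname(cls[, cc]), naive_overlap(regions, feats[[cc]]),
                 info = cc)
  gene_or_prom <- naive_overlap(regions, feats$gene_body) |
    naive_overlap(regions, feats$promoter)
  expect_equal(unname(cls[, "intergenic"]), !gene_or_prom)
  expect_equal(unname(cls[, "non_repeat"]),
               !naive_overlap(regions, feats$`repeat`))
})

test_that("context tables are invariant to feature input order", {
  ann <- build_genome_annotation(sim_config(n_chroms = 1,
                                            chrom_length = 1e5, seed = 4))
  feats <- gene_features(ann$genes)
  q <- ann$tiles[seq(1, 90, by = 7), .(chrom, start, end)]
  shuf <- lapply(feats, function(f) f[sample(nrow(f))])
  ld1 <- location_distribution(q, q, feats)
  ld2 <- location_distribution(q, q, shuf)
  expect_equal(ld1, ld2)
})

test_that("interval enrichment reproduces the textbook chi-square and
           falls back to Fisher", {
  bg <- data.table::data.table(chrom = "chr1", start = (0:99) * 1000)
  bg[, end := start + 1000]
  q <- bg[1:10]
  track_all <- bg[c(1:10, 11:50), .(chrom, start, end)]  # 10/10 and 40/90
  res <- interval_enrichment(q, list(t1 = track_all), bg)
  tab <- matrix(c(10, 0, 40, 50), 2, byrow = TRUE)
  expect_equal(res$statistic,
               unname(suppressWarnings(
                 chisq.test(tab, correct = FALSE))$statistic))
  expect_equal(res$method, "chisq")
  # equal hit rates: statistic ~ 0, p ~ 1
  track_prop <- bg[c(1:5, 11:55), .(chrom, start, end)]  # 5/10 vs 45/90
  res2 <- interval_enrichment(q, list(t = track_prop), bg)
  expect_lt(res2$statistic, 1e-10)
  expect_gt(res2$p, 0.99)
  # tiny expected cell -> Fisher fallback, flagged
  track_rare <- bg[1, .(chrom, start, end)]
  res3 <- interval_enrichment(q, list(t = track_rare), bg)
  expect_equal(res3$method, "fisher")
  # three tracks -> three BH q-values
  res4 <- interval_enrichment(q, list(a = track_all, b = track_prop,
                                      c = track_rare), bg)
  expect_equal(res4$q, bh_ref(res4$p), tolerance = 1e-12)
  expect_error(interval_enrichment(bg[95:100][, start := start + 1],
                                   list(a = track_all), bg), "subset")
})
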