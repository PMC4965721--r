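test_that("module detection recovers planted correlation blocks", {
  # two blocks of 50 with strong within-block correlation, 50 noise vars
  bm <- simulate_block_matrices(n_var = 150, n_samples = 40,
                                blocks = list(
                                  list(vars = 1:50, shared = TRUE, sign = 1),
                                  list(vars = 51:100, shared = FALSE,
                                       sign = 1)),
                                noise_sd = 1/3, seed = 100)
  ms <- detect_modules(bm$a, min_size = 30)
  expect_equal(length(ms$modules), 2L)
  lab <- ms$membership$module
  truth <- bm$truth
  # Rand index vs planted truth
  pairs <- utils::combn(length(lab), 2)
  same_t <- truth[pairs[1, ]] == truth[pairs[2, ]]
  same_l <- lab[pairs[1, ]] == lab[pairs[2, ]]
  rand <- mean(same_t == same_l)
  expect_gte(rand, 0.95)
  # i.i.d. noise at min_size 30 yields no module
  noise <- matrix(rnorm(100 * 30), 100,
                  dimnames = list(sprintf("v%03d", 1:100), NULL))
  ms0 <- detect_modules(noise, min_size = 30)
  expect_equal(length(ms0$modules), 0L)
  expect_true(all(ms0$membership$module == 0L))
  # duplicated variables are perfectly correlated -> same module
  dup <- bm$a[c(1:40, 1:40), ]
  rownames(dup) <- sprintf("d%03d", 1:80)
  msd <- detect_modules(dup, min_size = 30)
  expect_equal(length(unique(msd$membership$module)), 1L)
  expect_true(all(msd$membership$module == 1L))
})

test_that("constant rows are dropped with a warning before correlation", {
  m <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(sprintf("v%02d", 1:40), NULL))
  m[3, ] <- 1
  expect_warning(ms <- detect_modules(m, min_size = 5), "constant")
  expect_false("v03" %in% ms$membership$variable_id)
})

test_that("eigengenes behave as first principal components", {
  set.seed(12)
  f <- rnorm(20)
  x <- matrix(rep(f, each = 10), 10, 20,
              dimnames = list(sprintf("v%02d", 1:10), sprintf("s%02d", 1:20)))
  e <- module_eigengene(x, rownames(x))
  expect_equal(abs(cor(e, f)), 1, tolerance = 1e-12)
  expect_true(all(cor(e, t(x)) > 0.999))        # sign anchor
  expect_equal(sum(e^2), 1)                     # unit norm
  expect_equal(module_eigengene(-x, rownames(x)), -e, tolerance = 1e-12)
  # scaling one member leaves the eigengene unchanged (standardization)
  x2 <- x + matrix(rnorm(200, 0, 0.05), 10, 20)
  e2 <- module_eigengene(x2, rownames(x2))
  x3 <- x2; x3[1, ] <- 100 * x3[1, ]
  expect_equal(abs(cor(module_eigengene(x3, rownames(x3)), e2)), 1,
               tolerance = 1e-10)
  # factor recovery under noise
  bm <- simulate_block_matrices(n_var = 60, n_samples = 25,
                                blocks = list(list(vars = 1:50,
                                                   shared = FALSE,
                                                   sign = 1)),
                                noise_sd = 0.1, seed = 5)
  ms <- detect_modules(bm$a, min_size = 20)
  latent <- colMeans(bm$a[1:50, ])  # proxy for the shared factor
  expect_gte(abs(cor(ms$eigengenes[1, ], latent)), 0.95)
  expect_error(module_eigengene(x[, 1:2], rownames(x)), "3 samples")
})

test_that("cross-tabulation overlap p matches subset enumeration", {
  u <- sprintf("g%02d", 1:10)
  a <- list(m1 = u[1:5])
  b <- list(m1 = u[1:5])
  res <- crosstab_overlap(a, b, u)
  expect_equal(res$fisher_p, 1 / 252, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:25) {
    un <- sample(8:20, 1)
    sa <- sample(2:(un - 2), 1); sb <- sample(2:(un - 2), 1)
    A <- sample(un, sa); B <- sample(un, sb)
    ov <- length(intersect(A, B))
    ids <- sprintf("v%02d", 1:un)
    p <- crosstab_overlap(list(m = ids[sort(A)]), list(m = ids[sort(B)]),
                          ids)$fisher_p
    # oracle: exhaustive enumeration over all size-|B| subsets
    expect_equal(p, enum_overlap_p(ov, sa, sb, un), tolerance = 1e-10,
                 info = paste(un, sa, sb, ov))
  }
  # disjoint small modules: p ~ 1; identical sets: diagonal maximal
  expect_gt(crosstab_overlap(list(m = u[1:2]), list(m = u[9:10]),
                             u)$fisher_p, 0.5)
  expect_error(crosstab_overlap(list(m = u[6:10]), list(m = u[1:5]),
                                u[1:8]), "universe")
  two <- crosstab_overlap(list(m1 = u[1:4], m2 = u[5:8]),
                          list(m1 = u[1:4], m2 = u[5:8]), u)
  expect_equal(two[two$module_a == two$module_b]$overlap, c(4L, 4L))
  expect_equal(two[two$module_a != two$module_b]$overlap, c(0L, 0L))
})

test_that("enum_overlap_p oracle sanity: symmetric in A and B", {
  expect_equal(enum_overlap_p(2, 4, 3, 10), enum_overlap_p(2, 3, 4, 10),
               tolerance = 1e-12)
})

test_that("preservation Z separates preserved, shared and null structure", {
  bm <- simulate_block_matrices(n_var = 150, n_samples = 40,
                                blocks = list(
                                  list(vars = 1:50, shared = TRUE,
                                       sign = -1),
                                  list(vars = 51:100, shared = FALSE,
                                       sign = 1)),
                                noise_sd = 1/3, seed = 200)
  ms <- detect_modules(bm$a, min_size = 30)
  expect_equal(length(ms$modules), 2L)
  # identical matrices: strong evidence for every module; the connectivity
  # statistic is degenerate there (its permutation distribution has no
  # spread) and is flagged
  w <- capture_warnings(pz_same <- preservation_z(ms, bm$a, bm$a,
                                                  n_perm = 60, seed = 1))
  expect_true(length(w) >= 1 && all(grepl("degenerate", w)))
  expect_true(all(pz_same$Z_summary > 10))
  # shared block preserved in b, non-shared not
  pz <- preservation_z(ms, bm$a, bm$b, n_perm = 100, seed = 2)
  shared_mod <- ms$membership[variable_id == "var_001"]$module
  other_mod <- ms$membership[variable_id == "var_051"]$module
  expect_gt(pz[pz$module == shared_mod]$Z_summary, 10)
  expect_lt(pz[pz$module == other_mod]$Z_summary, 2)
  expect_true(all(pz$medianRank >= 1))
  # sample-permuted test matrix: no evidence anywhere
  set.seed(3)
  b_perm <- t(apply(bm$b, 1, sample))
  dimnames(b_perm) <- dimnames(bm$b)
  pz0 <- preservation_z(ms, bm$a, b_perm, n_perm = 100, seed = 4)
  expect_true(all(pz0$Z_summary > -2 & pz0$Z_summary < 2))
})

test_that("preservation Z is calibrated near zero under the null", {
  zs <- sapply(1:10, function(i) {
    bm <- simulate_block_matrices(n_var = 60, n_samples = 30,
                                  blocks = list(list(vars = 1:30,
                                                     shared = FALSE,
                                                     sign = 1)),
                                  noise_sd = 1/3, seed = 300 + i)
    ms <- detect_modules(bm$a, min_size = 20)
    pz <- preservation_z(ms, bm$a, bm$b, n_perm = 50, seed = i)
    mean(pz$Z_summary)
  })
  expect_gt(mean(zs), -1)
  expect_lt(mean(zs), 1)
})

test_that("eigengene correlations expose shared latent factors", {
  bm <- simulate_block_matrices(n_var = 150, n_samples = 40,
                                blocks = list(
                                  list(vars = 1:50, shared = TRUE,
                                       sign = -1),
                                  list(vars = 51:100, shared = FALSE,
                                       sign = 1)),
                                noise_sd = 1/3, seed = 200)
  msa <- detect_modules(bm$a, min_size = 30)
  msb <- detect_modules(bm$b, min_size = 30)
  expect_gte(length(msb$modules), 1L)
  ec <- eigengene_correlation(msa, msb)
  shared_a <- as.character(msa$membership[variable_id == "var_001"]$module)
  shared_b <- as.character(msb$membership[variable_id == "var_001"]$module)
  r_shared <- ec[module_a == shared_a & module_b == shared_b]$r
  expect_gt(abs(r_shared), 0.8)
  expect_lt(r_shared, 0)  # sign = -1 coupling
  # module against itself correlates exactly 1
  self <- eigengene_correlation(msa, msa)
  expect_equal(self[module_a == module_b]$r, rep(1, length(msa$modules)))
  # sample mismatch errors
  msb2 <- msb
  colnames(msb2$eigengenes) <- rev(colnames(msb2$eigengenes))
  expect_error(eigengene_correlation(msa, msb2), "order")
})

test_that("module detection is invariant to variable input order", {
  bm <- simulate_block_matrices(n_var = 120, n_samples = 40,
                                noise_sd = 1/3, seed = 7)
  ms1 <- detect_modules(bm$a, min_size = 30)
  perm <- sample(nrow(bm$a))
  ms2 <- detect_modules(bm$a[perm, ], min_size = 30)
  m1 <- ms1$membership[order(variable_id)]
  m2 <- ms2$membership[order(variable_id)]
  # same partition up to label names
  expect_equal(length(ms1$modules), length(ms2$modules))
  tab <- table(m1$module, m2$module)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("differential matrices pair transcripts with 3'UTR coverage", {
  coh <- std_cohort()
  feats <- gene_features(coh$annotation$genes)
  cases <- coh$sim$case_ids[1:5]
  dm <- build_differential_matrices(coh$expression, coh$sim$coverage, feats,
                                    cases, coh$sim$control_ids[1])
  expect_identical(colnames(dm$expr), cases)
  expect_identical(rownames(dm$expr), rownames(dm$meth))
  expect_false(anyNA(dm$expr))
  expect_false(anyNA(dm$meth))
  # hand-check one cell
  tx <- rownames(dm$meth)[1]
  m_case <- class_methylation(coh$sim$coverage, feats, "utr3",
                              sample_ids = cases[1])
  m_ctrl <- class_methylation(coh$sim$coverage, feats, "utr3",
                              sample_ids = coh$sim$control_ids[1])
  expect_equal(dm$meth[tx, 1],
               100 * (m_case[transcript_id == tx]$level -
                        m_ctrl[transcript_id == tx]$level))
  expect_equal(dm$expr[tx, 1],
               log2((coh$expression[tx, cases[1]] + 1) /
                      (coh$expression[tx, coh$sim$control_ids[1]] + 1)))
  expect_error(build_differential_matrices(coh$expression,
                                           coh$sim$coverage, feats, cases,
                                           "nope"), "control")
})
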