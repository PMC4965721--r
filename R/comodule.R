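#' Build paired differential expression / differential 3'UTR-methylation
#' matrices
#'
#' For each case sample versus one common control sample:
#' methylation differential = mean 3'UTR CpG methylation difference
#' (percentage points); expression differential =
#' `log2((FPKM_case + 1) / (FPKM_control + 1))`. Transcripts are restricted
#' to those with 3'UTR CpG coverage in the control and every case sample and
#' with expression data, so both matrices are complete over the same
#' transcript universe.
#'
#' @param expression matrix transcripts x samples (cases + control).
#' @param coverage named list of per-sample coverage tables.
#' @param features output of [gene_features()] (needs `utr3`).
#' @param case_ids,control_id sample ids.
#' @return list `expr`, `meth`: matrices transcripts x case samples.
#' @export
build_differential_matrices <- function(expression, coverage, features,
                                        case_ids, control_id) {
  if (!control_id %in% colnames(expression) ||
      !control_id %in% names(coverage))
    stop("no common control sample '", control_id, "' in both data sets")
  per_sample <- lapply(c(case_ids, control_id), function(s)
    class_methylation(coverage, features, "utr3", sample_ids = s))
  names(per_sample) <- c(case_ids, control_id)
  tx <- Reduce(intersect, lapply(per_sample, `[[`, "transcript_id"))
  tx <- intersect(tx, rownames(expression))
  if (!length(tx)) stop("no transcripts with joint 3'UTR coverage and ",
                        "expression")
  meth <- sapply(case_ids, function(s) {
    m <- per_sample[[s]]; ctl <- per_sample[[control_id]]
    100 * (m$level[match(tx, m$transcript_id)] -
             ctl$level[match(tx, ctl$transcript_id)])
  })
  expr <- sapply(case_ids, function(s)
    log2((expression[tx, s] + 1) / (expression[tx, control_id] + 1)))
  rownames(meth) <- rownames(expr) <- tx
  list(expr = expr, meth = meth)
}

adjacency <- function(mat, beta = 6) {
  abs(cor(t(mat)))^beta
}

#' Detect correlation-network modules
#'
#' Simplified weighted-correlation clustering: adjacency
#' `|cor(x_i, x_j)|^beta`, dissimilarity `1 - adjacency`, average-linkage
#' hierarchical clustering, flat cut at `cut_height`; clusters smaller than
#' `min_size` are pooled into the unassigned "grey" pool (module 0). Module
#' labels are integers by decreasing size with conventional color aliases.
#'
#' @param mat matrix variables x samples.
#' @param beta soft-threshold power.
#' @param cut_height flat tree-cut height on the dissimilarity dendrogram.
#' @param min_size minimum module size.
#' @return Object of class `module_set`: list with `membership` (data.table
#'   variable_id, module, color), `modules` (named list of member ids),
#'   `eigengenes` (modules x samples matrix), `mat` reference, `params`.
#' @export
detect_modules <- function(mat, beta = 6, cut_height = 0.75, min_size = 30L) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L, ncol(mat) >= 3L)
  sds <- apply(mat, 1L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant variable row(s) dropped before ",
            "correlation")
    mat <- mat[sds > 0, , drop = FALSE]
  }
  a <- adjacency(mat, beta)
  d <- 1 - a
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  cl <- cutree(hc, h = cut_height)
  sizes <- sort(table(cl), decreasing = TRUE)
  big <- names(sizes)[sizes >= min_size]
  module <- integer(length(cl))
  for (k in seq_along(big)) module[cl == as.integer(big[k])] <- k
  colors <- c("grey", "turquoise", "blue", "brown", "yellow", "green",
              "red", "black", "pink", "magenta", "purple", "greenyellow",
              "tan", "salmon", "cyan", "midnightblue", "lightcyan",
              "grey60", "lightgreen", "lightyellow", "royalblue")
  membership <- data.table::data.table(
    variable_id = rownames(mat), module = module,
    color = colors[pmin(module + 1L, length(colors))])
  mods <- split(rownames(mat), module)
  mods <- mods[names(mods) != "0"]
  eig <- NULL
  if (length(mods)) {
    eig <- t(sapply(mods, function(v) module_eigengene(mat, v)))
    rownames(eig) <- names(mods)
    colnames(eig) <- colnames(mat)
  }
  out <- list(membership = membership, modules = mods, eigengenes = eig,
              mat = mat,
              params = list(beta = beta, cut_height = cut_height,
                            min_size = min_size))
  class(out) <- "module_set"
  out
}

#' Module eigengene
#'
#' First principal component over samples of the module's standardized
#' (per-variable z-scored) submatrix: the first right-singular vector, unit
#' norm, sign anchored so that its mean correlation with the member
#' variables is non-negative.
#'
#' @param mat matrix variables x samples.
#' @param members member variable ids (rownames of `mat`), at least 2.
#' @return numeric eigengene vector (length = samples).
#' @export
module_eigengene <- function(mat, members) {
  if (ncol(mat) < 3L) stop("need at least 3 samples for an eigengene")
  stopifnot(length(members) >= 2L, all(members %in% rownames(mat)))
  x <- mat[members, , drop = FALSE]
  xz <- t(scale(t(x)))
  xz[is.na(xz)] <- 0
  sv <- svd(xz, nu = 0L, nv = 1L)
  e <- sv$v[, 1L]
  e <- e / sqrt(sum(e^2))
  cors <- suppressWarnings(cor(e, t(x)))
  if (mean(cors, na.rm = TRUE) < 0) e <- -e
  setNames(e, colnames(mat))
}

#' Cross-tabulation overlap of two module sets
#'
#' For every pair of (non-grey) modules from the two sets over the same
#' variable universe, the hypergeometric upper-tail p-value of the member
#' overlap (Fisher's one-sided exact test), BH-adjusted across all pairs.
#'
#' @param ms_a,ms_b `module_set` objects (or named lists of member ids).
#' @param universe character vector of all variable ids (both sets must
#'   cover exactly this universe).
#' @return data.table: module_a, module_b, size_a, size_b, overlap,
#'   fisher_p, fisher_q.
#' @export
crosstab_overlap <- function(ms_a, ms_b, universe) {
  mods_a <- if (inherits(ms_a, "module_set")) ms_a$modules else ms_a
  mods_b <- if (inherits(ms_b, "module_set")) ms_b$modules else ms_b
  symdiff_n <- function(ms, mods) {
    if (inherits(ms, "module_set")) {
      v <- ms$membership$variable_id
      length(setdiff(v, universe)) + length(setdiff(universe, v))
    } else length(setdiff(unique(unlist(mods)), universe))
  }
  nd <- symdiff_n(ms_a, mods_a) + symdiff_n(ms_b, mods_b)
  if (nd > 0)
    stop("module sets and universe disagree (symmetric difference of ",
         nd, " variables)")
  U <- length(universe)
  rows <- list()
  for (na in names(mods_a)) for (nb in names(mods_b)) {
    A <- mods_a[[na]]; B <- mods_b[[nb]]
    ov <- length(intersect(A, B))
    p <- stats::phyper(ov - 1L, length(A), U - length(A), length(B),
                       lower.tail = FALSE)
    rows[[paste(na, nb)]] <- data.table::data.table(
      module_a = na, module_b = nb, size_a = length(A),
      size_b = length(B), overlap = ov, fisher_p = p)
  }
  out <- data.table::rbindlist(rows)
  out[, fisher_q := bh_fdr(fisher_p)]
  out[]
}

preservation_stats <- function(members, a_ref, a_test) {
  idx <- members
  sub_t <- a_test[idx, idx, drop = FALSE]
  k <- length(idx)
  density <- (sum(sub_t) - k) / (k * (k - 1))  # mean off-diagonal adjacency
  sub_r <- a_ref[idx, idx, drop = FALSE]
  k_ref <- rowSums(sub_r) - 1
  k_test <- rowSums(sub_t) - 1
  conn <- suppressWarnings(cor(k_ref, k_test))
  c(density = density, connectivity = conn)
}

#' Permutation preservation statistics for reference modules in a test
#' matrix
#'
#' Density statistic: mean off-diagonal adjacency among module members in
#' the test matrix. Connectivity statistic: correlation of the members'
#' intramodular connectivity (adjacency row sums) between reference and test
#' matrices. The permutation null redraws module-sized random variable sets
#' from the shared universe; `Z = (obs - mean_perm) / sd_perm` per statistic,
#' `Z_summary` is the mean of the (non-degenerate) component Z scores, and
#' `medianRank` is the per-module median of
#' the two observed statistics' ranks across modules (rank 1 = strongest; no
#' permutations involved).
#'
#' @param ms reference `module_set`.
#' @param ref_mat,test_mat matrices variables x samples over the same
#'   variable universe.
#' @param beta adjacency power.
#' @param n_perm random sets per module.
#' @param seed integer seed.
#' @return data.table: module, size, obs_density, obs_connectivity,
#'   Z_density, Z_connectivity, Z_summary, medianRank.
#' @export
preservation_z <- function(ms, ref_mat, test_mat, beta = 6, n_perm = 100L,
                           seed = 1L) {
  stopifnot(inherits(ms, "module_set"))
  if (!setequal(rownames(ref_mat), rownames(test_mat)))
    stop("reference and test matrices must share the variable universe")
  test_mat <- test_mat[rownames(ref_mat), , drop = FALSE]
  set.seed(seed)
  a_ref <- adjacency(ref_mat, beta)
  a_test <- adjacency(test_mat, beta)
  vars <- rownames(ref_mat)
  rows <- list()
  for (nm in names(ms$modules)) {
    members <- intersect(ms$modules[[nm]], vars)
    k <- length(members)
    obs <- preservation_stats(members, a_ref, a_test)
    perm <- replicate(n_perm, preservation_stats(sample(vars, k),
                                                 a_ref, a_test))
    mu <- rowMeans(perm); sdv <- apply(perm, 1L, sd)
    # a statistic whose permutation distribution has (numerically) no
    # spread carries no information: report its Z as missing
    degenerate <- sdv < 1e-8 * pmax(abs(mu), 1)
    z <- (obs - mu) / sdv
    if (any(degenerate)) {
      warning("degenerate permutation distribution for module ", nm,
              "; Z set to NA")
      z[degenerate] <- NA_real_
    }
    rows[[nm]] <- data.table::data.table(
      module = nm, size = k,
      obs_density = obs[["density"]],
      obs_connectivity = obs[["connectivity"]],
      Z_density = z[["density"]], Z_connectivity = z[["connectivity"]],
      Z_summary = if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
  }
  out <- data.table::rbindlist(rows)
  rk_d <- rank(-out$obs_density, ties.method = "average")
  rk_c <- rank(-out$obs_connectivity, ties.method = "average")
  out[, medianRank := apply(cbind(rk_d, rk_c), 1L, stats::median)]
  out[]
}

#' All-pairs eigengene correlations between two module sets
#'
#' Pearson correlation (two-sided test, BH-adjusted) between every pair of
#' module eigengenes from two module sets computed over the same samples in
#' the same order.
#'
#' @param ms_a,ms_b `module_set` objects with eigengenes.
#' @return data.table: module_a, module_b, r, p, q.
#' @export
eigengene_correlation <- function(ms_a, ms_b) {
  stopifnot(inherits(ms_a, "module_set"), inherits(ms_b, "module_set"))
  ea <- ms_a$eigengenes; eb <- ms_b$eigengenes
  if (is.null(ea) || is.null(eb)) stop("module set without eigengenes")
  if (!identical(colnames(ea), colnames(eb)))
    stop("sample ids/order differ between the two module sets")
  rows <- list()
  for (na in rownames(ea)) for (nb in rownames(eb)) {
    ct <- cor.test(ea[na, ], eb[nb, ], method = "pearson")
    rows[[paste(na, nb)]] <- data.table::data.table(
      module_a = na, module_b = nb, r = unname(ct$estimate), p = ct$p.value)
  }
  out <- data.table::rbindlist(rows)
  out[, q := bh_fdr(p)]
  out[]
}

#' Simulate paired matrices with planted correlated blocks
#'
#' Benchmark generator for the module-comparison machinery: two matrices
#' (e.g. differential methylation and differential expression) over a shared
#' variable universe. Each planted block is driven by a latent per-sample
#' factor; shared blocks place the same factor (optionally sign-flipped) in
#' both matrices, so the block pair is preserved across data sets.
#' Background variables are i.i.d. noise.
#'
#' @param n_var number of variables.
#' @param n_samples number of samples.
#' @param blocks list of lists with fields `vars` (indices), `shared`
#'   (logical), `sign` (+1/-1 coupling sign in matrix B), `loading` (factor
#'   loading, default 1).
#' @param noise_sd residual noise sd.
#' @param seed integer seed.
#' @return list `a`, `b` (matrices), `truth` (block membership integer
#'   vector, 0 = background).
#' @export
simulate_block_matrices <- function(n_var = 150L, n_samples = 20L,
                                    blocks = list(
                                      list(vars = 1:50, shared = TRUE,
                                           sign = -1),
                                      list(vars = 51:100, shared = FALSE,
                                           sign = 1)),
                                    noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("var_%03d", seq_len(n_var))
  a <- matrix(rnorm(n_var * n_samples, 0, 1), n_var, n_samples,
              dimnames = list(ids, sprintf("s%02d", seq_len(n_samples))))
  b <- matrix(rnorm(n_var * n_samples, 0, 1), n_var, n_samples,
              dimnames = dimnames(a))
  truth <- integer(n_var)
  for (k in seq_along(blocks)) {
    bl <- blocks[[k]]
    loading <- if (is.null(bl$loading)) 1 else bl$loading
    f <- rnorm(n_samples)
    v <- bl$vars
    truth[v] <- k
    a[v, ] <- loading * matrix(rep(f, each = length(v)), length(v)) +
      matrix(rnorm(length(v) * n_samples, 0, noise_sd), length(v))
    if (isTRUE(bl$shared)) {
      b[v, ] <- bl$sign * loading *
        matrix(rep(f, each = length(v)), length(v)) +
        matrix(rnorm(length(v) * n_samples, 0, noise_sd), length(v))
    }
  }
  list(a = a, b = b, truth = setNames(truth, ids))
}
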