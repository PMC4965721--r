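#' Count per-region consistent calls in one direction
#'
#' @param call integer call matrix (tiles x case samples; +1 hyper, -1 hypo,
#'   0 ns, NA invalid).
#' @param direction "hyper" or "hypo".
#' @return integer vector of per-region counts (NA calls count as not called).
#' @export
count_consistent <- function(call, direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  v <- if (direction == "hyper") 1L else -1L
  rowSums(call == v, na.rm = TRUE)
}

#' Empirical per-direction background call rate
#'
#' The binomial null probability `p0`: the fraction of (region, case sample)
#' cells carrying a significant call in the given direction, clipped to
#' `[1e-6, 1 - 1e-6]`.
#'
#' @param call integer call matrix restricted to the common-region set.
#' @param direction "hyper" or "hypo".
#' @return scalar rate.
#' @export
estimate_null_rate <- function(call, direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  n <- sum(!is.na(call))
  if (n == 0L) stop("no calls available to estimate the background rate")
  v <- if (direction == "hyper") 1L else -1L
  min(max(sum(call == v, na.rm = TRUE) / n, 1e-6), 1 - 1e-6)
}

#' Binomial cross-sample consistency test
#'
#' For regions called in the same direction in at least `k_min` of `n_total`
#' case samples, the one-sided upper-tail binomial probability
#' `P(X >= n_consistent | X ~ Binomial(n_total, p0))`, BH-adjusted over the
#' tested regions. Regions below `k_min` are not tested.
#'
#' @param n_consistent integer vector of per-region consistent-call counts.
#' @param n_total number of case samples.
#' @param k_min minimum consistent count for testing.
#' @param p0 binomial null probability, in (0, 1).
#' @param q_thresh significance threshold on the adjusted p.
#' @return data.table: n_consistent, tested, binom_p, binom_q, significant.
#' @export
binomial_consistency <- function(n_consistent, n_total, k_min = 25L, p0,
                                 q_thresh = 0.01) {
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1)
    stop("p0 must be a single probability strictly inside (0, 1)")
  stopifnot(all(n_consistent >= 0), all(n_consistent <= n_total))
  tested <- n_consistent >= k_min
  p <- rep(NA_real_, length(n_consistent))
  p[tested] <- pbinom(n_consistent[tested] - 1L, n_total, p0,
                      lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  q[tested] <- bh_fdr(p[tested])
  data.table::data.table(n_consistent = as.integer(n_consistent),
                         tested = tested, binom_p = p, binom_q = q,
                         significant = !is.na(q) & q < q_thresh)
}

#' Intersect per-control-batch consistency results into C-DMRs
#'
#' A region is a C-DMR in a direction iff its binomial consistency is
#' significant in every control batch. Batches over different region
#' universes trigger a warning; the intersection is computed on the shared
#' universe.
#'
#' @param batch_results list (one per control batch) of data.tables with
#'   columns `tile_id`, `direction`, `significant`.
#' @return data.table `tile_id`, `direction`, `is_cdmr` over the shared
#'   universe (region x direction pairs present in all batches).
#' @export
intersect_control_batches <- function(batch_results) {
  stopifnot(length(batch_results) >= 1L)
  if (length(batch_results) == 1L)
    message("single control batch: C-DMR set equals that batch's list")
  keys <- lapply(batch_results, function(b) paste(b$tile_id, b$direction))
  shared <- Reduce(intersect, keys)
  if (any(lengths(keys) != length(shared)))
    warning("control batches cover different region universes; ",
            "intersecting on the shared universe")
  tab <- data.table::rbindlist(lapply(batch_results, function(b)
    b[paste(b$tile_id, b$direction) %in% shared,
      .(tile_id, direction, significant)]))
  out <- tab[, .(is_cdmr = all(significant)), by = .(tile_id, direction)]
  out[]
}

# all-pairs precomputation for the sample permutation test:
# call[t, i, j] = DMR call of sample i (as case) vs sample j (as control)
all_pairs_calls <- function(tm, q_thresh = 0.01, diff_thresh = 25) {
  samples <- colnames(tm$total)
  n <- nrow(tm$regions); m <- length(samples)
  call <- array(NA_integer_, c(n, m, m),
                dimnames = list(tm$regions$tile_id, samples, samples))
  for (i in seq_len(m - 1L)) {
    for (j in seq((i + 1L), m)) {
      res <- fisher_dmr(tm$meth[, i], tm$total[, i],
                        tm$meth[, j], tm$total[, j],
                        q_thresh = q_thresh, diff_thresh = diff_thresh)
      v <- data.table::fcase(res$call == "hyper", 1L,
                             res$call == "hypo", -1L,
                             res$call == "ns", 0L)
      call[, i, j] <- v
      call[, j, i] <- -v
    }
  }
  call
}

# permutation statistic: per region and direction, the minimum over control
# batches of the consistent-call count (the quantity the C-DMR intersection
# thresholds); tiles invalid under a permuted labelling contribute 0.
perm_min_count <- function(call_pairs, ctrl_idx, case_idx, direction) {
  v <- if (direction == "hyper") 1L else -1L
  counts <- sapply(ctrl_idx, function(j) {
    rowSums(call_pairs[, case_idx, j, drop = FALSE] == v, na.rm = TRUE)
  })
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = length(ctrl_idx))
  apply(counts, 1L, min)
}

#' Sample-label permutation test for C-DMR consistency
#'
#' Each permutation reassigns the control labels uniformly at random among
#' all samples (keeping group sizes), recomputes every pairwise DMR call and
#' the per-region consistent-sample count, and compares the minimum count
#' across the permuted control batches with the observed one. Empirical
#' p-values use the add-one rule `(1 + #{perm >= obs}) / (1 + n_perm)` and
#' are BH-adjusted over the tested regions.
#'
#' @param tm a [tile_matrix()] over all samples.
#' @param case_ids,control_ids original labels.
#' @param observed data.table `tile_id`, `direction`, `obs` (observed minimum
#'   consistent count across batches) for the tested regions.
#' @param n_perm number of permutations (at least 19).
#' @param seed integer seed.
#' @param q_thresh,diff_thresh DMR call thresholds.
#' @return `observed` with columns `perm_p`, `perm_q` appended.
#' @export
permute_samples <- function(tm, case_ids, control_ids, observed,
                            n_perm = 100L, seed = 1L, q_thresh = 0.01,
                            diff_thresh = 25) {
  if (n_perm < 19L) stop("n_perm must be at least 19 to reach p < 0.05")
  set.seed(seed)
  samples <- colnames(tm$total)
  stopifnot(setequal(samples, c(case_ids, control_ids)))
  call_pairs <- all_pairs_calls(tm, q_thresh, diff_thresh)
  ti <- match(observed$tile_id, tm$regions$tile_id)
  stopifnot(!anyNA(ti))
  exceed <- rep(0L, nrow(observed))
  m <- length(samples); nc <- length(control_ids)
  for (b in seq_len(n_perm)) {
    ctrl <- sample.int(m, nc)
    case <- setdiff(seq_len(m), ctrl)
    for (d in c("hyper", "hypo")) {
      rows <- which(observed$direction == d)
      if (!length(rows)) next
      stat <- perm_min_count(call_pairs, ctrl, case, d)[ti[rows]]
      exceed[rows] <- exceed[rows] + (stat >= observed$obs[rows])
    }
  }
  out <- data.table::copy(observed)
  out[, perm_p := (1 + exceed) / (1 + n_perm)]
  out[, perm_q := bh_fdr(perm_p)]
  out[]
}

#' Region permutation test for C-DMR consistency
#'
#' Each permutation shuffles, independently within each case sample (and
#' within each control batch), the per-region DMR calls across the common
#' regions, then recomputes the per-region consistent-call counts and the
#' minimum across batches. Empirical p-values use the add-one rule and BH
#' adjustment as in [permute_samples()].
#'
#' @param batches list of [compare_cohort()] results (one per control).
#' @param observed data.table `tile_id`, `direction`, `obs` as in
#'   [permute_samples()].
#' @param n_perm number of permutations (at least 19).
#' @param seed integer seed.
#' @return `observed` with `perm_p`, `perm_q` appended.
#' @export
permute_regions <- function(batches, observed, n_perm = 100L, seed = 1L) {
  if (n_perm < 19L) stop("n_perm must be at least 19 to reach p < 0.05")
  set.seed(seed)
  universe <- Reduce(intersect, lapply(batches, function(b)
    b$regions$tile_id[b$common]))
  calls <- lapply(batches, function(b)
    b$call[match(universe, b$regions$tile_id), , drop = FALSE])
  ti <- match(observed$tile_id, universe)
  stopifnot(!anyNA(ti))
  n <- length(universe)
  exceed <- rep(0L, nrow(observed))
  for (b in seq_len(n_perm)) {
    shuffled <- lapply(calls, function(cm)
      apply(cm, 2L, function(col) col[sample.int(n)]))
    for (d in c("hyper", "hypo")) {
      rows <- which(observed$direction == d)
      if (!length(rows)) next
      v <- if (d == "hyper") 1L else -1L
      counts <- sapply(shuffled, function(cm) rowSums(cm == v, na.rm = TRUE))
      stat <- apply(counts, 1L, min)[ti[rows]]
      exceed[rows] <- exceed[rows] + (stat >= observed$obs[rows])
    }
  }
  out <- data.table::copy(observed)
  out[, perm_p := (1 + exceed) / (1 + n_perm)]
  out[, perm_q := bh_fdr(perm_p)]
  out[]
}

#' Full C-DMR calling: pairwise DMRs, binomial consistency, batch
#' intersection and permutation validation
#'
#' @param tm a [tile_matrix()] over cases and controls.
#' @param case_ids,control_ids sample ids.
#' @param dmr_q,diff_thresh per-pair DMR call thresholds.
#' @param k_min,binom_q binomial consistency parameters.
#' @param p0 `"empirical"` (per-batch, per-direction background rate), or a
#'   fixed numeric probability.
#' @param n_perm permutations for the two validation tests (0 skips them).
#' @param perm_q significance threshold on permutation q-values.
#' @param seed seed for the permutation tests.
#' @return Object of class `cdmr_result`: list with `results` (per region x
#'   direction consistency table), `batches`, `params`. In `results`,
#'   `is_cdmr` requires binomial significance in every batch, at least
#'   `k_min` consistent samples, and (when permutations ran) both
#'   permutation q below `perm_q`.
#' @export
call_cdmr <- function(tm, case_ids, control_ids, dmr_q = 0.01,
                      diff_thresh = 25, k_min = 25L, binom_q = 0.01,
                      p0 = "empirical", n_perm = 100L, perm_q = 0.05,
                      seed = 1L) {
  stopifnot(inherits(tm, "tile_matrix"))
  batches <- lapply(control_ids, function(ctrl)
    compare_cohort(tm, case_ids, ctrl, q_thresh = dmr_q,
                   diff_thresh = diff_thresh))
  names(batches) <- control_ids
  universe <- Reduce(intersect, lapply(batches, function(b)
    b$regions$tile_id[b$common]))

  per_batch <- list()
  for (ctrl in control_ids) {
    b <- batches[[ctrl]]
    cm <- b$call[match(universe, b$regions$tile_id), , drop = FALSE]
    for (d in c("hyper", "hypo")) {
      n_cons <- count_consistent(cm, d)
      rate <- if (identical(p0, "empirical")) {
        if (any(n_cons >= k_min)) estimate_null_rate(cm, d) else NA_real_
      } else as.numeric(p0)
      bc <- if (is.na(rate)) {
        data.table::data.table(n_consistent = as.integer(n_cons),
                               tested = FALSE, binom_p = NA_real_,
                               binom_q = NA_real_, significant = FALSE)
      } else binomial_consistency(n_cons, length(case_ids), k_min, rate,
                                  binom_q)
      bc[, `:=`(tile_id = universe, direction = d, control_id = ctrl,
                p0 = rate)]
      per_batch[[paste(ctrl, d)]] <- bc
    }
  }
  long <- data.table::rbindlist(per_batch)
  cdmr <- intersect_control_batches(
    split(long[, .(tile_id, direction, significant)],
          long$control_id))
  res <- data.table::dcast(
    long, tile_id + direction ~ control_id,
    value.var = c("n_consistent", "binom_q"))
  res <- merge(res, cdmr, by = c("tile_id", "direction"))
  ncols <- grep("^n_consistent_", names(res), value = TRUE)
  res[, n_consistent := do.call(pmin, .SD), .SDcols = ncols]
  res[, is_cdmr := is_cdmr & n_consistent >= k_min]

  if (n_perm > 0L) {
    tested <- res[n_consistent >= k_min,
                  .(tile_id, direction, obs = n_consistent)]
    if (nrow(tested)) {
      ps <- permute_samples(tm, case_ids, control_ids, tested,
                            n_perm = n_perm, seed = seed,
                            q_thresh = dmr_q, diff_thresh = diff_thresh)
      pr <- permute_regions(batches, tested, n_perm = n_perm,
                            seed = seed + 1L)
      res <- merge(res, ps[, .(tile_id, direction,
                               perm_sample_p = perm_p,
                               perm_sample_q = perm_q)],
                   by = c("tile_id", "direction"), all.x = TRUE)
      res <- merge(res, pr[, .(tile_id, direction,
                               perm_region_p = perm_p,
                               perm_region_q = perm_q)],
                   by = c("tile_id", "direction"), all.x = TRUE)
      res[, is_cdmr := is_cdmr & !is.na(perm_sample_q) &
            perm_sample_q < perm_q & perm_region_q < perm_q]
    } else {
      res[, `:=`(perm_sample_p = NA_real_, perm_sample_q = NA_real_,
                 perm_region_p = NA_real_, perm_region_q = NA_real_)]
    }
  }
  reg <- tm$regions[match(res$tile_id, tm$regions$tile_id)]
  res[, `:=`(chrom = reg$chrom, start = reg$start, end = reg$end)]
  out <- list(results = res[], batches = batches,
              params = list(dmr_q = dmr_q, diff_thresh = diff_thresh,
                            k_min = k_min, binom_q = binom_q, p0 = p0,
                            n_perm = n_perm, perm_q = perm_q, seed = seed),
              universe = universe)
  class(out) <- "cdmr_result"
  out
}
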