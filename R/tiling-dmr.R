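#' Read a per-CpG bisulfite coverage table
#'
#' Expects a 4-column TSV (`chrom  pos  meth_reads  total_reads`, 0-based CpG
#' positions; a header line is accepted). Records are returned sorted by
#' (chrom, pos); duplicate positions are merged by count summation with a
#' warning.
#'
#' @param path file path.
#' @return data.table with chrom, pos, meth_reads, total_reads.
#' @export
read_coverage <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  has_header <- length(first) >= 4L && is.na(suppressWarnings(as.numeric(first[2])))
  dt <- data.table::fread(path, header = has_header, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) != 4L)
    stop("coverage file must have 4 columns (chrom, pos, meth_reads, ",
         "total_reads): ", path)
  data.table::setnames(dt, c("chrom", "pos", "meth_reads", "total_reads"))
  for (col in c("pos", "meth_reads", "total_reads")) {
    v <- dt[[col]]
    if (!is.numeric(v) || any(v != floor(v)))
      stop("non-integer values in column '", col, "' of ", path)
    data.table::set(dt, j = col, value = as.integer(v))
  }
  bad <- which(dt$meth_reads > dt$total_reads | dt$meth_reads < 0)
  if (length(bad))
    stop("meth_reads > total_reads at line ", bad[1] + has_header,
         " of ", path)
  if (anyDuplicated(dt, by = c("chrom", "pos"))) {
    warning("duplicate CpG positions in ", path, "; merging by count summation")
    dt <- dt[, .(meth_reads = sum(meth_reads),
                 total_reads = sum(total_reads)), by = .(chrom, pos)]
  }
  data.table::setorder(dt, chrom, pos)
  dt[]
}

#' Aggregate per-CpG counts onto fixed genomic tiles
#'
#' Tiles are `[k * tile_size, (k + 1) * tile_size)` per chromosome. A CpG
#' contributes only if its total reads reach `min_depth`; a tile is retained
#' only if at least `min_cpgs` CpGs contribute. Pooled methylated/total counts
#' are summed over contributing CpGs.
#'
#' @param cpgs coverage table for one sample ([read_coverage()] output).
#' @param tile_size tile width in bp.
#' @param min_cpgs minimum contributing CpGs per retained tile.
#' @param min_depth minimum reads per contributing CpG.
#' @return data.table: chrom, start, end, n_cpgs, meth_reads, total_reads,
#'   level (pooled methylation fraction).
#' @export
aggregate_tiles <- function(cpgs, tile_size = 1000L, min_cpgs = 3L,
                            min_depth = 10L) {
  dt <- cpgs[total_reads >= min_depth]
  if (!nrow(dt))
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_cpgs = integer(),
                                  meth_reads = integer(),
                                  total_reads = integer(), level = numeric()))
  dt[, start := (pos %/% as.integer(tile_size)) * as.integer(tile_size)]
  out <- dt[, .(n_cpgs = .N, meth_reads = sum(meth_reads),
                total_reads = sum(total_reads)), by = .(chrom, start)]
  out <- out[n_cpgs >= min_cpgs]
  out[, end := start + as.integer(tile_size)]
  out[, level := meth_reads / total_reads]
  data.table::setorder(out, chrom, start)
  data.table::setcolorder(out, c("chrom", "start", "end", "n_cpgs",
                                 "meth_reads", "total_reads", "level"))
  out[]
}

#' Assemble per-sample tile tables into count matrices
#'
#' @param tile_list named list (sample id -> [aggregate_tiles()] output).
#' @return Object of class `tile_matrix`: list with `regions` (tile table),
#'   `meth`, `total`, `level` (tiles x samples matrices; NA where a tile was
#'   not retained for a sample).
#' @export
tile_matrix <- function(tile_list) {
  stopifnot(length(tile_list) >= 1L, !is.null(names(tile_list)))
  all <- data.table::rbindlist(tile_list, idcol = "sample")
  regions <- unique(all[, .(chrom, start, end)])
  data.table::setorder(regions, chrom, start)
  regions[, tile_id := paste0(chrom, ":", start)]
  key <- regions$tile_id
  samples <- names(tile_list)
  meth <- total <- matrix(NA_integer_, nrow(regions), length(samples),
                          dimnames = list(key, samples))
  for (s in samples) {
    t <- tile_list[[s]]
    i <- match(paste0(t$chrom, ":", t$start), key)
    meth[i, s] <- t$meth_reads
    total[i, s] <- t$total_reads
  }
  out <- list(regions = regions, meth = meth, total = total,
              level = meth / total)
  class(out) <- "tile_matrix"
  out
}

#' Vectorized two-sided Fisher exact test for 2x2 methylation tables
#'
#' p-values for tables `[[meth_case, unmeth_case], [meth_ctrl, unmeth_ctrl]]`
#' using the standard "point probability at most the observed" two-sided
#' rule. Tables with a zero total in either sample are undefined (NA).
#'
#' @param meth_case,total_case,meth_ctrl,total_ctrl integer vectors.
#' @return numeric vector of p-values.
#' @export
fisher_test_2x2 <- function(meth_case, total_case, meth_ctrl, total_ctrl) {
  fisher2x2_p_cpp(as.integer(meth_case),
                  as.integer(total_case - meth_case),
                  as.integer(meth_ctrl),
                  as.integer(total_ctrl - meth_ctrl))
}

#' Benjamini-Hochberg q-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` so the pipeline's FDR
#' convention is named and testable in one place.
#'
#' @param p numeric vector of p-values (NA allowed).
#' @return q-values, same length.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric())
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

#' Per-tile DMR calls for one case/control sample pair
#'
#' Fisher two-sided p per tile, percentage-point methylation difference
#' (case minus control), BH q over the tiles valid in this comparison, and a
#' call: `hyper` (q below threshold and diff at least `diff_thresh`), `hypo`
#' (symmetric), else `ns`.
#'
#' @param meth_case,total_case,meth_ctrl,total_ctrl pooled tile counts.
#' @param q_thresh q-value threshold for a call.
#' @param diff_thresh minimum absolute methylation difference (percentage
#'   points) for a call.
#' @return data.table: p, q, diff, call.
#' @export
fisher_dmr <- function(meth_case, total_case, meth_ctrl, total_ctrl,
                       q_thresh = 0.01, diff_thresh = 25) {
  p <- fisher_test_2x2(meth_case, total_case, meth_ctrl, total_ctrl)
  diff <- 100 * (meth_case / total_case - meth_ctrl / total_ctrl)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- bh_fdr(p[ok])
  call <- rep("ns", length(p))
  call[ok & q < q_thresh & diff >= diff_thresh] <- "hyper"
  call[ok & q < q_thresh & diff <= -diff_thresh] <- "hypo"
  call[!ok] <- NA_character_
  data.table::data.table(p = p, q = q, diff = diff, call = call)
}

#' Pairwise DMR calls of every case against one control sample
#'
#' Runs [fisher_dmr()] for each (case, control) pair over the tiles valid in
#' that pair (retained in both samples), with FDR computed within each
#' comparison. The common-region set is the tiles with a valid call in every
#' case-versus-this-control comparison; downstream consistency statistics are
#' restricted to it.
#'
#' @param tm a [tile_matrix()].
#' @param case_ids,control_id sample ids (columns of `tm`).
#' @param q_thresh,diff_thresh call thresholds, see [fisher_dmr()].
#' @return Object of class `dmr_batch`: list with `regions`, `control_id`,
#'   `case_ids`, matrices `p`, `q`, `diff` and integer `call` (+1 hyper,
#'   -1 hypo, 0 ns, NA invalid) of shape tiles x cases, logical `common`,
#'   and `params`.
#' @export
compare_cohort <- function(tm, case_ids, control_id, q_thresh = 0.01,
                           diff_thresh = 25) {
  stopifnot(inherits(tm, "tile_matrix"), length(control_id) == 1L,
            length(case_ids) >= 1L)
  miss <- setdiff(c(case_ids, control_id), colnames(tm$total))
  if (length(miss)) stop("samples absent from tile matrix: ",
                         paste(miss, collapse = ", "))
  tc <- tm$total[, control_id]
  if (all(is.na(tc) | tc == 0)) stop("control tile table is empty")
  n <- nrow(tm$regions)
  pm <- qm <- dm <- matrix(NA_real_, n, length(case_ids),
                           dimnames = list(tm$regions$tile_id, case_ids))
  cm <- matrix(NA_integer_, n, length(case_ids),
               dimnames = list(tm$regions$tile_id, case_ids))
  for (s in case_ids) {
    res <- fisher_dmr(tm$meth[, s], tm$total[, s],
                      tm$meth[, control_id], tc,
                      q_thresh = q_thresh, diff_thresh = diff_thresh)
    pm[, s] <- res$p; qm[, s] <- res$q; dm[, s] <- res$diff
    cm[, s] <- data.table::fcase(res$call == "hyper", 1L,
                                 res$call == "hypo", -1L,
                                 res$call == "ns", 0L)
  }
  out <- list(regions = tm$regions, control_id = control_id,
              case_ids = case_ids, p = pm, q = qm, diff = dm, call = cm,
              common = rowSums(is.na(cm)) == 0L,
              params = list(q_thresh = q_thresh, diff_thresh = diff_thresh))
  class(out) <- "dmr_batch"
  out
}

#' Flatten a `dmr_batch` into a long DMR table
#'
#' @param batch a [compare_cohort()] result.
#' @param calls_only keep only hyper/hypo calls.
#' @return data.table: chrom, start, end, case_id, control_id, diff, p, q,
#'   call.
#' @export
dmr_table <- function(batch, calls_only = FALSE) {
  stopifnot(inherits(batch, "dmr_batch"))
  out <- data.table::rbindlist(lapply(batch$case_ids, function(s) {
    data.table::data.table(
      chrom = batch$regions$chrom, start = batch$regions$start,
      end = batch$regions$end, case_id = s, control_id = batch$control_id,
      diff = batch$diff[, s], p = batch$p[, s], q = batch$q[, s],
      call = c("hypo", "ns", "hyper")[batch$call[, s] + 2L])
  }))
  if (calls_only) out <- out[call %in% c("hyper", "hypo")]
  out[]
}
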