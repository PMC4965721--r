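#' Shannon methylation entropy of one region across samples
#'
#' The methylation vector `m` (one value per case sample: levels or absolute
#' differences) is normalized to a probability distribution
#' `p_s = m_s / sum(m)` and the entropy `H = -sum p_s log2 p_s` is returned
#' in bits. Zero entries contribute nothing; a vector summing to zero has
#' undefined entropy (NA). `H` lies in `[0, log2(N)]`, attaining the maximum
#' iff all entries are equal.
#'
#' @param m non-negative numeric vector.
#' @return entropy in bits, or NA.
#' @export
region_entropy <- function(m) {
  stopifnot(is.numeric(m))
  if (any(is.na(m))) return(NA_real_)
  if (any(m < 0)) stop("methylation vector must be non-negative")
  tot <- sum(m)
  if (tot == 0) return(NA_real_)
  p <- m[m > 0] / tot
  -sum(p * log2(p))
}

#' Per-region methylation entropy table for one control batch
#'
#' For every common region of a batch, builds the cross-case methylation
#' vector — by default the absolute case-minus-control methylation
#' difference (`input_kind = "diff"`), or the raw case methylation level
#' (`"level"`) — and computes its Shannon entropy plus the mean signed
#' methylation difference (percentage points).
#'
#' @param tm a [tile_matrix()].
#' @param case_ids,control_id sample ids.
#' @param input_kind "diff" (absolute differences) or "level" (raw levels).
#' @param regions optional character vector of tile ids to restrict to
#'   (e.g. a batch's common-region set); default: tiles covered in the
#'   control and all cases.
#' @return data.table: tile_id, chrom, start, end, H, mean_change, n_samples.
#' @export
entropy_table <- function(tm, case_ids, control_id,
                          input_kind = c("diff", "level"), regions = NULL) {
  input_kind <- match.arg(input_kind)
  stopifnot(inherits(tm, "tile_matrix"))
  lv <- tm$level
  keep <- if (is.null(regions)) {
    rowSums(is.na(lv[, c(case_ids, control_id), drop = FALSE])) == 0L
  } else tm$regions$tile_id %in% regions
  cl <- lv[keep, case_ids, drop = FALSE]
  ct <- lv[keep, control_id]
  dif <- 100 * (cl - ct)
  m <- if (input_kind == "diff") abs(dif) else 100 * cl
  H <- apply(m, 1L, region_entropy)
  reg <- tm$regions[keep]
  data.table::data.table(tile_id = reg$tile_id, chrom = reg$chrom,
                         start = reg$start, end = reg$end, H = H,
                         mean_change = rowMeans(dif),
                         n_samples = length(case_ids))
}

#' Correlation between methylation entropy and mean methylation change
#'
#' Pearson correlation (two-sided test) between per-region entropy and the
#' absolute mean methylation change, over regions with defined entropy.
#'
#' @param records an [entropy_table()] result (columns H, mean_change).
#' @return list with `r`, `p`, `n` (`r`/`p` NA when degenerate).
#' @export
entropy_change_correlation <- function(records) {
  ok <- !is.na(records$H) & !is.na(records$mean_change)
  H <- records$H[ok]; x <- abs(records$mean_change[ok])
  if (length(H) < 3L) stop("need at least 3 regions with defined entropy")
  if (sd(H) == 0 || sd(x) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(H)))
  ct <- cor.test(H, x, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(H))
}
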