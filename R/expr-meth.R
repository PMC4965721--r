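#' Read an expression table
#'
#' Accepts a wide matrix TSV (`transcript_id` column plus one column per
#' sample) or a long 3-column TSV (`transcript_id  sample_id  fpkm`).
#'
#' @param path file path.
#' @return numeric matrix transcripts x samples.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  if (ncol(dt) == 3L &&
      all(names(dt) %in% c("transcript_id", "sample_id", "fpkm"))) {
    wide <- data.table::dcast(dt, transcript_id ~ sample_id,
                              value.var = "fpkm")
  } else wide <- dt
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide[[1]]
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values")
  m
}

#' Assign expression quartiles
#'
#' Rank-based split into four near-equal groups Q1 (lowest) .. Q4 (highest);
#' ties are broken by stable input order, so group sizes differ by at most 1.
#'
#' @param x per-transcript expression summary (e.g. mean over case samples).
#' @return factor of labels Q1..Q4, same length/names as `x`.
#' @export
assign_quartiles <- function(x) {
  if (length(x) < 4L) stop("need at least 4 transcripts for quartiles")
  r <- rank(x, ties.method = "first")
  q <- ceiling(4 * r / length(x))
  factor(paste0("Q", q), levels = paste0("Q", 1:4))
}

# pooled per-CpG methylation across samples: sum counts, one row per CpG
pool_coverage <- function(coverage, sample_ids = names(coverage)) {
  all <- data.table::rbindlist(coverage[sample_ids])
  out <- all[, .(meth_reads = sum(meth_reads),
                 total_reads = sum(total_reads)), by = .(chrom, pos)]
  out[, level := meth_reads / total_reads]
  data.table::setorder(out, chrom, pos)
  out[]
}

#' Per-transcript mean methylation within a genic class
#'
#' Pools CpG counts across the given samples, intersects CpGs with the class
#' intervals of each transcript, and returns the pooled methylation level
#' per transcript.
#'
#' @param coverage named list of coverage tables.
#' @param features output of [gene_features()].
#' @param class genic class name (a `features` entry).
#' @param sample_ids samples to pool (default: all).
#' @return data.table: transcript_id, level, n_cpgs.
#' @export
class_methylation <- function(coverage, features, class,
                              sample_ids = names(coverage)) {
  stopifnot(class %in% names(features))
  pooled <- pool_coverage(coverage, sample_ids)
  f <- features[[class]]
  if (!nrow(f)) return(data.table::data.table(transcript_id = character(),
                                              level = numeric(),
                                              n_cpgs = integer()))
  cg <- GenomicRanges::GRanges(pooled$chrom,
                               IRanges::IRanges(pooled$pos + 1L,
                                                pooled$pos + 1L))
  ov <- GenomicRanges::findOverlaps(cg, dt_to_granges(f),
                                    ignore.strand = TRUE)
  if (!length(ov)) return(data.table::data.table(transcript_id = character(),
                                                 level = numeric(),
                                                 n_cpgs = integer()))
  hits <- data.table::data.table(
    transcript_id = f$transcript_id[S4Vectors::subjectHits(ov)],
    meth = pooled$meth_reads[S4Vectors::queryHits(ov)],
    total = pooled$total_reads[S4Vectors::queryHits(ov)],
    cpg = S4Vectors::queryHits(ov))
  out <- hits[, .(level = sum(meth) / sum(total),
                  n_cpgs = data.table::uniqueN(cpg)), by = transcript_id]
  out[]
}

#' Metagene / boundary methylation profile for one expression quartile
#'
#' Maps pooled CpG methylation onto relative coordinates over a genic unit
#' with flanks, strand-aware (positions are reflected on the minus strand),
#' bins them, and adds a LOESS-smoothed column (tri-cube local regression,
#' configurable span). For scaled units (`gene`, `utr5`, `utr3`, `exon`,
#' `intron`) the unit body maps to `[0, 1]` and each fixed-bp flank to a
#' 0.25-wide margin; boundary units (`exon_boundary`, `intron_boundary`) use
#' absolute bp offsets around interval starts/ends.
#'
#' @param coverage named list of coverage tables (case samples are pooled).
#' @param features output of [gene_features()].
#' @param transcripts transcript ids of the quartile.
#' @param unit one of gene, utr5, utr3, exon, intron, exon_boundary,
#'   intron_boundary.
#' @param n_bins body bins for scaled units.
#' @param flank flank width in bp (scaled units).
#' @param flank_bins bins per flank (scaled units).
#' @param boundary_bp,boundary_bin window and bin width for boundary units.
#' @param span LOESS span.
#' @param sample_ids samples to pool.
#' @return data.table: unit, bin, pos (bin center), mean_meth, smooth, n.
#' @export
metagene_profile <- function(coverage, features, transcripts,
                             unit = "gene", n_bins = 40L, flank = 2000L,
                             flank_bins = 10L, boundary_bp = 200L,
                             boundary_bin = 10L, span = 0.3,
                             sample_ids = names(coverage)) {
  units <- c("gene", "utr5", "utr3", "exon", "intron", "exon_boundary",
             "intron_boundary")
  unit <- match.arg(unit, units)
  pooled <- pool_coverage(coverage, sample_ids)
  cls <- switch(unit, gene = "gene_body", exon_boundary = "exon",
                intron_boundary = "intron", unit)
  f <- features[[cls]][features[[cls]]$transcript_id %in% transcripts]
  if (!nrow(f)) {
    warning("no ", unit, " intervals for this quartile; empty profile")
    return(data.table::data.table(unit = character(), bin = integer(),
                                  pos = numeric(), mean_meth = numeric(),
                                  smooth = numeric(), n = integer()))
  }
  boundary <- grepl("_boundary$", unit)
  xs <- list(); ms <- list()
  for (i in seq_len(nrow(f))) {
    s <- f$start[i]; e <- f$end[i]; minus <- f$strand[i] == "-"
    if (boundary) {
      for (edge in c(s, e)) {
        sel <- pooled[chrom == f$chrom[i] & pos >= edge - boundary_bp &
                        pos < edge + boundary_bp]
        if (!nrow(sel)) next
        off <- sel$pos - edge
        if (minus) off <- -off
        xs[[length(xs) + 1L]] <- off
        ms[[length(ms) + 1L]] <- sel$level
      }
    } else {
      sel <- pooled[chrom == f$chrom[i] & pos >= s - flank & pos < e + flank]
      if (!nrow(sel)) next
      w <- e - s
      rel <- ifelse(sel$pos < s, (sel$pos - s) / flank * 0.25,
                    ifelse(sel$pos >= e, 1 + (sel$pos - e + 1) / flank * 0.25,
                           (sel$pos - s) / w))
      if (minus) rel <- 1 - rel
      xs[[length(xs) + 1L]] <- rel
      ms[[length(ms) + 1L]] <- sel$level
    }
  }
  if (!length(xs)) {
    warning("no covered CpGs for this quartile; empty profile")
    return(data.table::data.table(unit = character(), bin = integer(),
                                  pos = numeric(), mean_meth = numeric(),
                                  smooth = numeric(), n = integer()))
  }
  x <- unlist(xs); m <- unlist(ms)
  if (boundary) {
    breaks <- seq(-boundary_bp, boundary_bp, by = boundary_bin)
  } else {
    breaks <- c(seq(-0.25, 0, length.out = flank_bins + 1L)[-(flank_bins + 1L)],
                seq(0, 1, length.out = n_bins + 1L)[-(n_bins + 1L)],
                seq(1, 1.25, length.out = flank_bins + 1L))
  }
  bin <- cut(x, breaks, include.lowest = TRUE, labels = FALSE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  prof <- data.table::data.table(bin = bin, m = m)[!is.na(bin),
    .(mean_meth = mean(m), n = .N), by = bin]
  data.table::setorder(prof, bin)
  prof[, pos := centers[bin]]
  sm <- rep(NA_real_, nrow(prof))
  if (nrow(prof) >= 4L) {
    fit <- tryCatch(loess(mean_meth ~ pos, data = prof, span = span,
                          degree = 1L, family = "gaussian"),
                    error = function(e) NULL)
    if (!is.null(fit)) sm <- as.numeric(predict(fit, prof$pos))
  }
  prof[, `:=`(smooth = sm, unit = unit)]
  data.table::setcolorder(prof, c("unit", "bin", "pos", "mean_meth",
                                  "smooth", "n"))
  prof[]
}

#' Per-genic-class methylation-expression Pearson correlation
#'
#' Pairs per-transcript pooled methylation in a genic class with the
#' per-transcript mean expression and reports the Pearson correlation with a
#' two-sided test.
#'
#' @param meth data.table transcript_id/level ([class_methylation()]).
#' @param expr_mean named numeric vector: mean expression per transcript.
#' @return list `r`, `p`, `n` (NA r/p on zero variance).
#' @export
region_class_correlation <- function(meth, expr_mean) {
  common <- intersect(meth$transcript_id, names(expr_mean))
  if (length(common) < 3L) stop("need at least 3 paired transcripts")
  x <- meth$level[match(common, meth$transcript_id)]
  y <- expr_mean[common]
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(common)))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}
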