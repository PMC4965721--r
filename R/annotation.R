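#' Read a gene-model table
#'
#' TSV with columns transcript_id, gene_id, chrom, strand, txStart, txEnd,
#' cdsStart, cdsEnd, exonStarts, exonEnds (comma-separated exon coordinate
#' lists; all coordinates 0-based half-open). A missing gene_id column is
#' filled with the transcript id.
#'
#' @param path file path.
#' @return data.table of gene models.
#' @export
read_gene_models <- function(path) {
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = c("exonStarts",
                                                          "exonEnds")))
  need <- c("transcript_id", "chrom", "strand", "txStart", "txEnd",
            "cdsStart", "cdsEnd", "exonStarts", "exonEnds")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("gene-model table missing columns: ", paste(miss, collapse = ", "))
  if (!"gene_id" %in% names(dt)) dt[, gene_id := transcript_id]
  dt
}

#' Select one reference isoform per gene
#'
#' For genes with multiple isoforms the longest transcript (largest
#' `txEnd - txStart`) is used as the reference; ties are broken by the
#' lexicographically smallest transcript id.
#'
#' @param models gene-model table ([read_gene_models()] layout).
#' @return gene-model table with one row per gene.
#' @export
select_reference_isoform <- function(models) {
  dt <- data.table::as.data.table(models)
  dt <- data.table::copy(dt)
  dt[, span := txEnd - txStart]
  data.table::setorder(dt, gene_id, -span, transcript_id)
  out <- dt[, .SD[1L], by = gene_id]
  out[, span := NULL]
  data.table::setcolorder(out, c("transcript_id", "gene_id"))
  out[]
}

parse_coord_list <- function(x) lapply(strsplit(as.character(x), ","),
                                       as.numeric)

#' Derive genomic feature intervals from gene models
#'
#' Builds, from the reference isoform of each gene, the promoter
#' (-2 kb..TSS, strand-aware), 5'UTR, exon, intron (gene span minus exons),
#' 3'UTR and gene-body interval sets. All intervals 0-based half-open.
#'
#' @param models gene-model table (any isoform set; reference isoforms are
#'   selected internally).
#' @return named list of data.tables (chrom, start, end, strand,
#'   transcript_id, gene_id) for classes promoter, utr5, exon, intron, utr3,
#'   gene_body.
#' @export
gene_features <- function(models) {
  ref <- select_reference_isoform(models)
  exS <- parse_coord_list(ref$exonStarts)
  exE <- parse_coord_list(ref$exonEnds)
  feats <- list(promoter = list(), utr5 = list(), exon = list(),
                intron = list(), utr3 = list(), gene_body = list())
  for (i in seq_len(nrow(ref))) {
    r <- ref[i]
    es <- exS[[i]]; ee <- exE[[i]]
    add <- function(cls, s, e) {
      keep <- e > s
      if (!any(keep)) return()
      feats[[cls]][[length(feats[[cls]]) + 1L]] <<- data.table::data.table(
        chrom = r$chrom, start = s[keep], end = e[keep], strand = r$strand,
        transcript_id = r$transcript_id, gene_id = r$gene_id)
    }
    if (r$strand == "+") add("promoter", max(0, r$txStart - 2000), r$txStart)
    else add("promoter", r$txEnd, r$txEnd + 2000)
    add("exon", es, ee)
    # UTRs: exonic sequence outside the CDS, strand-aware
    left <- data.table::data.table(s = pmax(es, r$txStart),
                                   e = pmin(ee, r$cdsStart))
    right <- data.table::data.table(s = pmax(es, r$cdsEnd),
                                    e = pmin(ee, r$txEnd))
    if (r$strand == "+") {
      add("utr5", left$s, left$e); add("utr3", right$s, right$e)
    } else {
      add("utr3", left$s, left$e); add("utr5", right$s, right$e)
    }
    # introns: gene span minus exons
    if (length(es) > 1L) add("intron", ee[-length(ee)], es[-1L])
    add("gene_body", r$txStart, r$txEnd)
  }
  lapply(feats, function(x)
    if (length(x)) data.table::rbindlist(x) else
      data.table::data.table(chrom = character(), start = numeric(),
                             end = numeric(), strand = character(),
                             transcript_id = character(),
                             gene_id = character()))
}

#' Classify regions by genomic context
#'
#' A feature class label is assigned iff the region overlaps at least 1 bp
#' of a class interval (classes are non-exclusive). `intergenic` means no
#' gene-body and no promoter overlap; `shore` means within 2 kb of a CpG
#' island (inclusive at exactly 2 kb) but not overlapping one; `non_repeat`
#' means no repeat overlap (emitted when a repeat track is supplied).
#'
#' @param regions data.table chrom/start/end (0-based half-open) or GRanges.
#' @param features named list of interval tables: output of
#'   [gene_features()], optionally extended with `cpg_island`, `repeat`,
#'   `enhancer` or other tracks.
#' @return logical matrix regions x classes.
#' @export
classify_region <- function(regions, features) {
  if (inherits(regions, "GRanges")) regions <- granges_to_dt(regions)
  regions <- data.table::as.data.table(regions)
  gr <- dt_to_granges(regions)
  feat_chroms <- unique(unlist(lapply(features, function(f)
    unique(as.character(f$chrom)))))
  bad <- setdiff(unique(regions$chrom), feat_chroms)
  if (length(bad))
    stop("region chromosome(s) absent from the feature set: ",
         paste(bad, collapse = ", "))
  classes <- names(features)
  out <- matrix(FALSE, nrow(regions), 0L)
  hit <- function(f) {
    if (!nrow(f)) return(rep(FALSE, nrow(regions)))
    IRanges::overlapsAny(gr, dt_to_granges(f), ignore.strand = TRUE)
  }
  for (cls in classes) out <- cbind(out, hit(features[[cls]]))
  colnames(out) <- classes
  if (all(c("gene_body", "promoter") %in% classes))
    out <- cbind(out, intergenic = !(out[, "gene_body"] | out[, "promoter"]))
  if ("cpg_island" %in% classes) {
    isl <- dt_to_granges(features$cpg_island)
    # distance to the nearest island (half-open gap; <= 2000 counts as shore)
    dmin <- rep(Inf, length(gr))
    ov <- GenomicRanges::findOverlaps(gr, isl, maxgap = 2001L,
                                      ignore.strand = TRUE)
    if (length(ov)) {
      dd <- GenomicRanges::distance(gr[S4Vectors::queryHits(ov)],
                                    isl[S4Vectors::subjectHits(ov)],
                                    ignore.strand = TRUE)
      agg <- tapply(dd, S4Vectors::queryHits(ov), min)
      dmin[as.integer(names(agg))] <- agg
    }
    out <- cbind(out, shore = !out[, "cpg_island"] & dmin <= 2000)
  }
  if ("repeat" %in% classes)
    out <- cbind(out, non_repeat = !out[, "repeat"])
  out
}

#' Context distribution of query regions against a background set
#'
#' Per feature class, the fraction of query regions overlapping at least one
#' class interval, and the same for the background regions. Classes are
#' non-exclusive, so fractions need not sum to 1.
#'
#' @param query,background region tables (chrom/start/end).
#' @param features as in [classify_region()].
#' @return data.table: class, query_frac, background_frac, query_n,
#'   background_n.
#' @export
location_distribution <- function(query, background, features) {
  if (!NROW(query)) stop("query region set is empty")
  if (!NROW(background)) stop("background region set is empty")
  qm <- classify_region(query, features)
  bm <- classify_region(background, features)
  data.table::data.table(class = colnames(qm),
                         query_frac = colMeans(qm),
                         background_frac = colMeans(bm),
                         query_n = colSums(qm),
                         background_n = colSums(bm))
}

#' Chi-square interval co-localization enrichment
#'
#' For each annotation track, tests whether query regions overlap the track
#' more (or less) often than the rest of the background universe, with a
#' 1-df chi-square on the 2x2 table `[[query hit, query miss],
#' [background-minus-query hit, miss]]`. When any expected cell drops below
#' 1 the test falls back to Fisher's exact test (flagged in the output).
#' p-values are BH-corrected across tracks.
#'
#' @param query region table; must be a subset of `background`.
#' @param tracks named list of interval tables.
#' @param background region table (the universe; includes the query).
#' @return data.table: track, query_hit, query_n, bg_hit, bg_n, statistic,
#'   p, q, method.
#' @export
interval_enrichment <- function(query, tracks, background) {
  query <- data.table::as.data.table(query)
  background <- data.table::as.data.table(background)
  qkey <- paste0(query$chrom, ":", query$start, "-", query$end)
  bkey <- paste0(background$chrom, ":", background$start, "-", background$end)
  if (!all(qkey %in% bkey))
    stop("query regions must be a subset of the background universe")
  qgr <- dt_to_granges(query)
  rest <- background[!bkey %in% qkey]
  rgr <- dt_to_granges(rest)
  rows <- lapply(names(tracks), function(nm) {
    tgr <- dt_to_granges(data.table::as.data.table(tracks[[nm]]))
    qh <- sum(IRanges::overlapsAny(qgr, tgr, ignore.strand = TRUE))
    rh <- sum(IRanges::overlapsAny(rgr, tgr, ignore.strand = TRUE))
    tab <- matrix(c(qh, nrow(query) - qh, rh, nrow(rest) - rh), 2L,
                  byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1)) {
      ft <- fisher.test(tab)
      data.table::data.table(track = nm, query_hit = qh,
                             query_n = nrow(query), bg_hit = rh,
                             bg_n = nrow(rest), statistic = NA_real_,
                             p = ft$p.value, method = "fisher")
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      data.table::data.table(track = nm, query_hit = qh,
                             query_n = nrow(query), bg_hit = rh,
                             bg_n = nrow(rest),
                             statistic = unname(ct$statistic),
                             p = ct$p.value, method = "chisq")
    }
  })
  out <- data.table::rbindlist(rows)
  out[, q := bh_fdr(p)]
  data.table::setcolorder(out, c("track", "query_hit", "query_n", "bg_hit",
                                 "bg_n", "statistic", "p", "q", "method"))
  out[]
}
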