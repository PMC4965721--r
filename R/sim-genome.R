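#' Build the toy genome annotation for a simulated cohort
#'
#' Lays out a deterministic (seeded) toy genome in repeating 10-tile gene
#' units. Each unit holds, in order along the unit and mirrored for minus
#' strand genes: 2 intergenic tiles, 2 promoter tiles (-2 kb to the TSS), one
#' 5'UTR/first-exon tile, 3 intron tiles, one coding-exon tile and one
#' 3'UTR/last-exon tile. A fraction of genes carry a CpG island spanning
#' -1 kb..+1 kb around the TSS; shores are the 2 kb island flanks. Repeat and
#' enhancer intervals are scattered over intergenic/intron tiles. Every fifth
#' gene gets a second, shorter isoform (for reference-isoform selection).
#' CpG positions are drawn uniformly within tiles. All intervals are 0-based
#' half-open.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `conmeth_annotation`: list with
#'   `tiles` (tile_id, chrom, start, end, context, in_island, gene_id),
#'   `cpgs` (chrom, pos, tile_id), `genes` (gene-model table:
#'   transcript_id, gene_id, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#'   exonStarts, exonEnds) and `tracks` (named list of interval tables for
#'   cpg_island, shore, repeat, enhancer, promoter).
#' @export
build_genome_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ts <- config$tile_size
  unit_bp <- 10 * ts
  units_per_chrom <- floor(config$chrom_length / unit_bp)
  if (units_per_chrom < 1L)
    stop("configuration error: chromosome too short for one gene unit")
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  n_units <- units_per_chrom * config$n_chroms

  tiles <- vector("list", n_units)
  genes <- vector("list", n_units)
  islands <- list(); repeats <- list(); enhancers <- list()
  g <- 0L
  island_draw <- runif(n_units) < config$island_fraction
  for (ci in seq_along(chroms)) {
    for (u in seq_len(units_per_chrom)) {
      g <- g + 1L
      us <- (u - 1L) * unit_bp
      strand <- if (g %% 2L == 1L) "+" else "-"
      gene_id <- sprintf("gene_%04d", g)
      if (strand == "+") {
        ctx <- c("intergenic", "intergenic", "promoter", "promoter", "utr5",
                 "intron", "intron", "intron", "exon", "utr3")
        txStart <- us + 4 * ts; txEnd <- us + 10 * ts
        cdsStart <- txStart + 0.4 * ts; cdsEnd <- us + 9.2 * ts
        exS <- c(txStart, us + 8 * ts); exE <- c(txStart + ts, txEnd)
        tss <- txStart
        isl <- c(us + 3 * ts, us + 5 * ts)
        intron_rep_tile <- us + 6 * ts
        enh_tile <- us + 7 * ts
      } else {
        ctx <- c("intergenic", "intergenic", "utr3", "exon", "intron",
                 "intron", "intron", "utr5", "promoter", "promoter")
        txStart <- us + 2 * ts; txEnd <- us + 8 * ts
        cdsStart <- txStart + 0.8 * ts; cdsEnd <- txEnd - 0.4 * ts
        exS <- c(txStart, txEnd - ts); exE <- c(txStart + 2 * ts, txEnd)
        tss <- txEnd
        isl <- c(us + 7 * ts, us + 9 * ts)
        intron_rep_tile <- us + 5 * ts
        enh_tile <- us + 4 * ts
      }
      tiles[[g]] <- data.table::data.table(
        chrom = chroms[ci], start = us + (0:9) * ts, context = ctx,
        in_island = island_draw[g] &
          (us + (0:9) * ts) >= isl[1] & (us + (0:9) * ts) < isl[2],
        gene_id = gene_id)
      tx <- data.table::data.table(
        transcript_id = sprintf("tx_%04d_1", g), gene_id = gene_id,
        chrom = chroms[ci], strand = strand,
        txStart = txStart, txEnd = txEnd,
        cdsStart = cdsStart, cdsEnd = cdsEnd,
        exonStarts = paste(exS, collapse = ","),
        exonEnds = paste(exE, collapse = ","))
      if (g %% 5L == 0L) {
        # shorter single-exon isoform, fully inside the gene span
        if (strand == "+") { s2 <- txStart; e2 <- txStart + 3 * ts }
        else { s2 <- txEnd - 3 * ts; e2 <- txEnd }
        tx2 <- data.table::copy(tx)
        tx2[, `:=`(transcript_id = sprintf("tx_%04d_2", g),
                   txStart = s2, txEnd = e2,
                   cdsStart = s2 + 0.2 * ts, cdsEnd = e2 - 0.2 * ts,
                   exonStarts = as.character(s2), exonEnds = as.character(e2))]
        tx <- rbind(tx, tx2)
      }
      genes[[g]] <- tx
      if (island_draw[g])
        islands[[length(islands) + 1L]] <-
          data.table::data.table(chrom = chroms[ci], start = isl[1], end = isl[2])
      if (g %% 2L == 0L) {
        repeats[[length(repeats) + 1L]] <- data.table::data.table(
          chrom = chroms[ci],
          start = c(us + 0.2 * ts, intron_rep_tile + 0.1 * ts),
          end = c(us + 0.7 * ts, intron_rep_tile + 0.6 * ts))
      }
      if (g %% 3L == 0L) {
        enhancers[[length(enhancers) + 1L]] <- data.table::data.table(
          chrom = chroms[ci], start = enh_tile + 0.3 * ts,
          end = enh_tile + 0.6 * ts)
      }
    }
  }
  tiles <- data.table::rbindlist(tiles)
  tiles[, end := start + ts]
  tiles[, tile_id := paste0(chrom, ":", start)]
  data.table::setcolorder(tiles, c("tile_id", "chrom", "start", "end",
                                   "context", "in_island", "gene_id"))
  genes <- data.table::rbindlist(genes)

  for (cls in c("promoter", "utr5", "exon", "intron", "utr3", "intergenic"))
    if (!any(tiles$context == cls))
      stop("configuration error: genic class '", cls, "' is empty")
  if (!length(islands))
    stop("configuration error: genic class 'cpg_island' is empty ",
         "(island_fraction too low for this genome size)")
  if (!length(repeats))
    stop("configuration error: track 'repeat' is empty")
  if (!length(enhancers))
    stop("configuration error: track 'enhancer' is empty")

  islands <- data.table::rbindlist(islands)
  shores <- data.table::data.table(
    chrom = rep(islands$chrom, 2L),
    start = c(pmax(0, islands$start - 2000), islands$end),
    end = c(islands$start, islands$end + 2000))
  data.table::setorder(shores, chrom, start)
  promoters <- promoter_intervals(genes)

  # CpG positions per tile (sorted, unique within tile)
  n_cpg <- sample(seq(config$cpgs_per_tile[1], config$cpgs_per_tile[2]),
                  nrow(tiles), replace = TRUE)
  cpgs <- tiles[rep(seq_len(.N), n_cpg),
                .(chrom, tile_start = start, tile_id)]
  offs <- unlist(lapply(n_cpg, function(k)
    sort(sample.int(ts, k, replace = FALSE) - 1L)), use.names = FALSE)
  cpgs[, pos := tile_start + offs]
  cpgs <- cpgs[, .(chrom, pos, tile_id)]
  data.table::setorder(cpgs, chrom, pos)

  ann <- list(tiles = tiles, cpgs = cpgs, genes = genes,
              tracks = list(cpg_island = islands, shore = shores,
                            `repeat` = data.table::rbindlist(repeats),
                            enhancer = data.table::rbindlist(enhancers),
                            promoter = promoters),
              config = config)
  class(ann) <- "conmeth_annotation"
  ann
}

# -2 kb promoter intervals, strand-aware, from a gene-model table
promoter_intervals <- function(models) {
  tss <- ifelse(models$strand == "+", models$txStart, models$txEnd)
  data.table::data.table(
    chrom = models$chrom,
    start = ifelse(models$strand == "+", pmax(0, tss - 2000), tss),
    end = ifelse(models$strand == "+", tss, tss + 2000),
    name = models$transcript_id,
    strand = models$strand)
}
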