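#' Write a simulated cohort to disk as plain-text fixture files
#'
#' Emits one coverage TSV per sample (`coverage/<sample>.tsv`: chrom, pos,
#' meth_reads, total_reads; 0-based CpG positions), BED tracks (0-based
#' half-open) for CpG islands, shores, repeats, enhancers and promoters, a
#' gene-model TSV, a wide expression TSV, the tile-level truth table and the
#' configuration as YAML. Everything round-trips losslessly through the
#' package readers.
#'
#' @param cohort a `conmeth_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "conmeth_cohort"))
  covdir <- file.path(dir, "coverage")
  ok <- dir.exists(covdir) || dir.create(covdir, recursive = TRUE)
  if (!ok || file.access(dir, 2L) != 0L)
    stop("cannot write fixture: directory '", dir, "' is not writable")
  for (s in names(cohort$sim$coverage))
    data.table::fwrite(cohort$sim$coverage[[s]],
                       file.path(covdir, paste0(s, ".tsv")), sep = "\t")
  ann <- cohort$annotation
  for (nm in names(ann$tracks)) {
    trk <- ann$tracks[[nm]]
    write_bed(trk, file.path(dir, paste0(sub("^repeat$", "repeats", nm), ".bed")))
  }
  data.table::fwrite(ann$genes, file.path(dir, "genes.tsv"), sep = "\t")
  expr <- data.table::as.data.table(cohort$expression, keep.rownames = "transcript_id")
  data.table::fwrite(expr, file.path(dir, "expression.tsv"), sep = "\t")
  data.table::fwrite(cohort$sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  cfg <- cohort$config
  cfg$planted <- lapply(cfg$planted, function(p) lapply(p, identity))
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return list with `coverage` (named list of coverage tables), `genes`,
#'   `tracks`, `expression` (matrix), `truth`, `config`.
#' @export
read_fixture <- function(dir) {
  covfiles <- list.files(file.path(dir, "coverage"), "\\.tsv$",
                         full.names = TRUE)
  coverage <- lapply(covfiles, read_coverage)
  names(coverage) <- sub("\\.tsv$", "", basename(covfiles))
  tracks <- list()
  for (nm in c("cpg_island", "shore", "repeats", "enhancer", "promoter")) {
    f <- file.path(dir, paste0(nm, ".bed"))
    if (file.exists(f))
      tracks[[sub("^repeats$", "repeat", nm)]] <- read_bed(f)
  }
  em <- NULL
  if (file.exists(file.path(dir, "expression.tsv"))) {
    expr <- data.table::fread(file.path(dir, "expression.tsv"))
    em <- as.matrix(expr[, -1])
    rownames(em) <- expr$transcript_id
  }
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  list(coverage = coverage,
       genes = read_gene_models(file.path(dir, "genes.tsv")),
       tracks = tracks, expression = em,
       truth = data.table::fread(file.path(dir, "truth.tsv")),
       config = cfg)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param x data.table/data.frame with chrom, start, end and optional name,
#'   score, strand columns, or a `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "GRanges")) x <- granges_to_dt(x)
  x <- data.table::copy(data.table::as.data.table(x))
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED columns are positional: pad name/score when strand is present
  if ("strand" %in% cols) {
    if (!"name" %in% cols) x[, name := "."]
    if (!"score" %in% cols) x[, score := 0]
    cols <- c("chrom", "start", "end", "name", "score", "strand")
  }
  out <- x[, ..cols]
  out[, `:=`(start = as.integer(start), end = as.integer(end))]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file into an interval table
#'
#' @param path BED file (0-based half-open, tab separated, no header).
#' @return data.table with chrom, start, end (+ name, score, strand if
#'   present).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, nm[seq_len(min(ncol(dt), 6L))])
  dt
}

granges_to_dt <- function(gr) {
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
}

# interval table (0-based half-open) -> GRanges (1-based closed internally)
dt_to_granges <- function(dt) {
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = if ("strand" %in% names(dt)) dt$strand else "*")
}
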