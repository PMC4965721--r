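#' Simulate per-sample CpG bisulfite counts with planted region classes
#'
#' Draws, for every sample and CpG, a total read count from a negative
#' binomial truncated below at the depth floor, and a methylated count from
#' `Binomial(total, theta)`, where the latent tile methylation `theta` is the
#' region-class baseline plus the planted effect (for carrier case samples)
#' plus per-(tile, sample) biological jitter. Effects act on the latent
#' probability, not on counts. Truth is recorded at tile resolution.
#'
#' RNG order (single stream seeded with `config$seed + 1`): planted tile
#' placement, carrier draws, case jitter, control jitter, then per-sample
#' read counts in sample order (cases then controls).
#'
#' @param config a [sim_config()].
#' @param annotation output of [build_genome_annotation()] for the same config.
#' @return Object of class `conmeth_sim`: list with `coverage` (named list of
#'   per-sample data.tables: chrom, pos, meth_reads, total_reads), `truth`
#'   (per-tile table: tile_id, chrom, start, end, context, in_island, class,
#'   effect, n_carriers, carriers), `theta` (latent tile-by-sample matrix),
#'   `case_ids`, `control_ids`.
#' @export
simulate_methylation <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "conmeth_annotation"))
  set.seed(config$seed + 1L)
  tiles <- data.table::copy(annotation$tiles)
  n_tiles <- nrow(tiles)
  cases <- case_ids(config); controls <- control_ids(config)
  samples <- c(cases, controls)

  tiles[, class := "null"]
  tiles[, effect := 0]
  tiles[, n_carriers := 0L]
  tiles[, carriers := ""]
  carrier_mat <- matrix(FALSE, n_tiles, config$n_case,
                        dimnames = list(tiles$tile_id, cases))
  taken <- rep(FALSE, n_tiles)
  for (p in config$planted) {
    elig <- tiles$context %in% p$context & !taken
    if (isTRUE(p$island_only)) elig <- elig & tiles$in_island
    idx <- which(elig)
    if (length(idx) < p$n)
      stop("not enough eligible tiles for planted class ", p$class,
           " (", length(idx), " < ", p$n, ")")
    sel <- sort(sample(idx, p$n))
    taken[sel] <- TRUE
    tiles[sel, `:=`(class = p$class, effect = p$effect)]
    k <- round(p$carrier_fraction * config$n_case)
    for (i in sel) {
      who <- sort(sample.int(config$n_case, k))
      carrier_mat[i, who] <- TRUE
    }
    tiles[sel, n_carriers := k]
    tiles[sel, carriers := apply(carrier_mat[sel, , drop = FALSE], 1,
                                 function(z) paste(cases[z], collapse = ","))]
  }

  base <- ifelse(tiles$in_island, config$baseline_meth[["cpg_island"]],
                 config$baseline_meth[tiles$context])
  theta <- matrix(rep(base, length(samples)), n_tiles, length(samples),
                  dimnames = list(tiles$tile_id, samples))
  theta[, cases] <- theta[, cases] + (tiles$effect / 100) * carrier_mat
  if (any(theta < 0 | theta > 1)) {
    warning("baseline + effect outside [0, 1]; clamping latent methylation")
    theta <- pmin(pmax(theta, 0), 1)
  }
  theta[, cases] <- theta[, cases] +
    matrix(rnorm(n_tiles * config$n_case, 0, config$case_sd),
           n_tiles, config$n_case)
  theta[, controls] <- theta[, controls] +
    matrix(rnorm(n_tiles * config$n_control, 0, config$control_sd),
           n_tiles, config$n_control)
  theta <- pmin(pmax(theta, 0.01), 0.99)

  cpgs <- annotation$cpgs
  tile_idx <- match(cpgs$tile_id, tiles$tile_id)
  n_cpg <- nrow(cpgs)
  coverage <- vector("list", length(samples))
  names(coverage) <- samples
  for (s in samples) {
    total <- rtrunc_nbinom(n_cpg, config$depth, config$depth_dispersion,
                           config$depth_floor)
    meth <- rbinom(n_cpg, total, theta[tile_idx, s])
    coverage[[s]] <- data.table::data.table(
      chrom = cpgs$chrom, pos = cpgs$pos,
      meth_reads = meth, total_reads = total)
  }

  out <- list(coverage = coverage, truth = tiles, theta = theta,
              case_ids = cases, control_ids = controls)
  class(out) <- "conmeth_sim"
  out
}

# negative binomial conditioned on >= floor via inverse-CDF sampling
rtrunc_nbinom <- function(n, mu, size, floor) {
  p0 <- pnbinom(floor - 1L, mu = mu, size = size)
  as.integer(qnbinom(runif(n, p0, 1), mu = mu, size = size))
}

#' Simulate a matched expression table
#'
#' Per-transcript, per-sample expression follows
#' `exp(base + sum_class coupling[class] * dmeth_class + noise)`, where
#' `dmeth_class` is the deviation of the sample's latent methylation from the
#' tile baseline, averaged over the gene's tiles of that class (fraction
#' units). Default coupling signs: promoter/5'UTR/exon negative, 3'UTR
#' positive, intron zero. Values are strictly positive (FPKM-like).
#'
#' Uses RNG stream seeded with `config$seed + 2`.
#'
#' @param config a [sim_config()].
#' @param annotation output of [build_genome_annotation()].
#' @param sim output of [simulate_methylation()].
#' @return matrix transcripts x samples (cases then controls).
#' @export
simulate_expression <- function(config, annotation, sim) {
  stopifnot(inherits(sim, "conmeth_sim"))
  known <- c("promoter", "utr5", "exon", "intron", "utr3")
  bad <- setdiff(names(config$coupling), known)
  if (length(bad))
    stop("unknown class in coupling map: ", paste(bad, collapse = ", "))
  set.seed(config$seed + 2L)
  truth <- sim$truth
  samples <- colnames(sim$theta)
  base <- ifelse(truth$in_island, config$baseline_meth[["cpg_island"]],
                 config$baseline_meth[truth$context])
  dmeth <- sim$theta - base  # tile x sample deviation from baseline

  models <- annotation$genes
  n_tx <- nrow(models)
  expr <- matrix(0, n_tx, length(samples),
                 dimnames = list(models$transcript_id, samples))
  base_expr <- rnorm(n_tx, config$expr_base_mean, config$expr_base_sd)
  # per-gene, per-class mean methylation deviation
  for (i in seq_len(n_tx)) {
    gid <- models$gene_id[i]
    sig <- 0
    for (cls in names(config$coupling)) {
      w <- config$coupling[[cls]]
      if (w == 0) next
      rows <- which(truth$gene_id == gid & truth$context == cls)
      if (!length(rows)) next
      sig <- sig + w * colMeans(dmeth[rows, , drop = FALSE])
    }
    expr[i, ] <- exp(base_expr[i] + sig +
                       rnorm(length(samples), 0, config$expr_noise_sd))
  }
  expr
}

#' Simulate a complete cohort (annotation, methylation, expression)
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, [write_fixture()] is called.
#' @return list with `annotation`, `sim`, `expression`, `config` (class
#'   `conmeth_cohort`).
#' @export
simulate_cohort <- function(config, dir = NULL) {
  ann <- build_genome_annotation(config)
  sim <- simulate_methylation(config, ann)
  expr <- simulate_expression(config, ann, sim)
  out <- list(annotation = ann, sim = sim, expression = expr, config = config)
  class(out) <- "conmeth_cohort"
  if (!is.null(dir)) write_fixture(out, dir)
  out
}
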