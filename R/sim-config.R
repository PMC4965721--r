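#' Simulation configuration for a synthetic bisulfite cohort
#'
#' Builds the configuration object consumed by [build_genome_annotation()],
#' [simulate_methylation()] and [simulate_expression()]. Defaults emulate the
#' shape of a small RRBS leukemia cohort: 30 case samples, 3 normal controls,
#' per-CpG counts over a toy genome tiled in 1000 bp windows, with planted
#' region classes.
#'
#' Planted classes:
#' \describe{
#'   \item{hyper_consistent / hypo_consistent}{moderate clonal shifts
#'     (default 40 percentage points) carried by almost all case samples
#'     (default 28/30); hyper effects are placed in CpG-island/promoter/5'UTR
#'     tiles, hypo effects in intron/3'UTR/intergenic tiles.}
#'   \item{hyper_sporadic / hypo_sporadic}{focal near-complete methylation
#'     switches (default 70 points) carried by a small subset of case samples
#'     (default 10/30).}
#'   \item{null}{every unplanted tile; effect 0.}
#' }
#'
#' @param n_case,n_control number of case / control samples.
#' @param n_chroms,chrom_length toy genome shape (chromosome count and length
#'   in bp; must be at least `10 * tile_size`).
#' @param tile_size analysis tile width in bp.
#' @param cpgs_per_tile integer range `c(lo, hi)`: CpG count drawn per tile.
#' @param depth mean reads per CpG; `depth_dispersion` is the negative-binomial
#'   size parameter; counts are truncated below at `depth_floor`.
#' @param depth_dispersion,depth_floor see `depth`.
#' @param baseline_meth named fractions in `[0, 1]`: latent methylation
#'   baseline per region class.
#' @param planted list of planted-region descriptors, each a list with fields
#'   `class`, `n`, `effect` (percentage points, signed), `carrier_fraction`,
#'   `context` (character vector of eligible tile contexts) and optional
#'   `island_only` flag. `NULL` plants nothing (a null cohort).
#' @param coupling named signed strengths linking per-class methylation change
#'   (fraction units) to log expression; classes must be among promoter, utr5,
#'   exon, intron, utr3.
#' @param case_sd,control_sd per-(tile, sample) biological jitter (sd of the
#'   latent methylation fraction) for case and control samples.
#'   `control_sd` is the control-heterogeneity knob.
#' @param expr_base_mean,expr_base_sd,expr_noise_sd log-scale expression
#'   baseline and noise.
#' @param island_fraction fraction of genes whose promoter/first-exon region
#'   carries a CpG island.
#' @param seed integer seed; every simulated output is bit-reproducible given
#'   the config.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_chroms = 1, chrom_length = 1e5, seed = 1)
sim_config <- function(n_case = 30L,
                       n_control = 3L,
                       n_chroms = 2L,
                       chrom_length = 5e5,
                       tile_size = 1000L,
                       cpgs_per_tile = c(4L, 10L),
                       depth = 80,
                       depth_dispersion = 5,
                       depth_floor = 10L,
                       baseline_meth = c(promoter = 0.15, cpg_island = 0.15,
                                         utr5 = 0.30, exon = 0.45,
                                         intron = 0.75, utr3 = 0.70,
                                         intergenic = 0.75),
                       planted = default_planted(n_case),
                       coupling = c(promoter = -1, utr5 = -2, exon = -1,
                                    intron = 0, utr3 = 2),
                       case_sd = 0.01,
                       control_sd = 0.02,
                       expr_base_mean = 3,
                       expr_base_sd = 0.7,
                       expr_noise_sd = 0.5,
                       island_fraction = 0.7,
                       seed = 1L) {
  cfg <- list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_chroms = as.integer(n_chroms), chrom_length = as.numeric(chrom_length),
    tile_size = as.integer(tile_size),
    cpgs_per_tile = as.integer(cpgs_per_tile),
    depth = depth, depth_dispersion = depth_dispersion,
    depth_floor = as.integer(depth_floor),
    baseline_meth = baseline_meth, planted = planted, coupling = coupling,
    case_sd = case_sd, control_sd = control_sd,
    expr_base_mean = expr_base_mean, expr_base_sd = expr_base_sd,
    expr_noise_sd = expr_noise_sd,
    island_fraction = island_fraction, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default planted-region layout (the standard benchmark fixture)
#'
#' 50 hyper- and 50 hypo-consistent regions (40-point effects, 28/30
#' carriers), 50 hyper- and 50 hypo-sporadic regions (70-point effects, 10/30
#' carriers); every other tile is null.
#'
#' @param n_case number of case samples (carrier counts scale off 30).
#' @return list of planted-region descriptors.
#' @export
default_planted <- function(n_case = 30L) {
  list(
    list(class = "hyper_consistent", n = 50L, effect = 40,
         carrier_fraction = 28 / 30, context = c("promoter", "utr5"),
         island_only = TRUE),
    list(class = "hypo_consistent", n = 50L, effect = -40,
         carrier_fraction = 28 / 30,
         context = c("intron", "utr3", "intergenic")),
    list(class = "hyper_sporadic", n = 50L, effect = 70,
         carrier_fraction = 10 / 30, context = c("promoter", "utr5"),
         island_only = TRUE),
    list(class = "hypo_sporadic", n = 50L, effect = -70,
         carrier_fraction = 10 / 30,
         context = c("intron", "utr3", "intergenic"))
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_case >= 1L, cfg$n_control >= 1L, cfg$n_chroms >= 1L,
            cfg$tile_size >= 100L)
  if (cfg$chrom_length < 10 * cfg$tile_size)
    stop("chrom_length must be at least 10 * tile_size")
  if (any(cfg$baseline_meth < 0 | cfg$baseline_meth > 1))
    stop("baseline_meth fractions must lie in [0, 1]")
  if (cfg$depth < cfg$depth_floor)
    stop("mean depth must be at least the depth floor (", cfg$depth_floor, ")")
  if (length(cfg$cpgs_per_tile) != 2L ||
      cfg$cpgs_per_tile[1] > cfg$cpgs_per_tile[2] || cfg$cpgs_per_tile[1] < 1L)
    stop("cpgs_per_tile must be an increasing positive integer pair")
  known <- c("promoter", "utr5", "exon", "intron", "utr3")
  bad <- setdiff(names(cfg$coupling), known)
  if (length(bad))
    stop("unknown class in coupling map: ", paste(bad, collapse = ", "))
  for (p in cfg$planted) {
    stopifnot(is.character(p$class), is.numeric(p$effect),
              p$carrier_fraction >= 0, p$carrier_fraction <= 1)
    if (!p$class %in% c("hyper_consistent", "hypo_consistent",
                        "hyper_sporadic", "hypo_sporadic"))
      stop("unknown planted class: ", p$class)
    consistent <- grepl("consistent", p$class)
    if (consistent && p$carrier_fraction < 25 / 30)
      stop("consistent classes require carrier_fraction >= 25/30")
    if (!consistent && p$carrier_fraction >= 0.5)
      stop("sporadic classes require carrier_fraction < 0.5")
    if (grepl("hyper", p$class) && p$effect <= 0)
      stop("hyper classes need a positive effect")
    if (grepl("hypo", p$class) && p$effect >= 0)
      stop("hypo classes need a negative effect")
  }
  invisible(cfg)
}

case_ids <- function(cfg) sprintf("case_%02d", seq_len(cfg$n_case))
control_ids <- function(cfg) sprintf("control_%d", seq_len(cfg$n_control))
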