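#' Default end-to-end run configuration
#'
#' Stage parameters default to the pipeline's standard thresholds: 1000 bp
#' tiles, minimum 3 CpGs and 10 reads per CpG, per-pair DMR q < 0.01,
#' binomial consistency in at least 25 case samples at q < 0.01, 100
#' permutations at q < 0.05.
#'
#' @param fixture_dir directory with input data ([write_fixture()] layout);
#'   `NULL` means simulate into `<out>/fixture` first.
#' @param out output directory.
#' @param ... overrides for any parameter.
#' @return named list of run parameters.
#' @export
run_config <- function(fixture_dir = NULL, out = "conmeth_run", ...) {
  cfg <- list(fixture_dir = fixture_dir, out = out,
              tile_size = 1000L, min_cpgs = 3L, min_depth = 10L,
              dmr_q = 0.01, diff_thresh = 25, k_min = 25L, cdmr_q = 0.01,
              p0 = "empirical", n_perm = 100L, perm_q = 0.05,
              entropy_kind = "diff", beta = 6, cut_height = 0.75,
              min_size = 30L, seed = 1L, sim_config = NULL)
  modifyList(cfg, list(...))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the whole pipeline end-to-end
#'
#' Executes simulate (optional) -> tiling/DMR -> C-DMR consistency ->
#' entropy -> annotation -> expression profiles -> co-modules, writing each
#' stage's tables as TSV under the output directory plus a YAML manifest
#' (stages, parameters, seed, input checksums).
#'
#' @param config a [run_config()] list.
#' @return manifest list, invisibly.
#' @export
run_all <- function(config = run_config()) {
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- character()

  if (is.null(config$fixture_dir)) {
    run_stage("simulate", {
      sc <- config$sim_config
      if (is.null(sc)) sc <- sim_config(seed = config$seed)
      config$fixture_dir <- file.path(out, "fixture")
      simulate_cohort(sc, dir = config$fixture_dir)
    })
    stages <- c(stages, "simulate")
  }
  fx <- run_stage("load", read_fixture(config$fixture_dir))
  cases <- grep("^case", names(fx$coverage), value = TRUE)
  controls <- grep("^control", names(fx$coverage), value = TRUE)
  if (!length(controls)) stop("stage 'load' failed: no control samples")

  tm <- run_stage("dmr", {
    tiles <- lapply(fx$coverage, aggregate_tiles,
                    tile_size = config$tile_size,
                    min_cpgs = config$min_cpgs,
                    min_depth = config$min_depth)
    tile_matrix(tiles)
  })
  stages <- c(stages, "dmr")

  cd <- run_stage("cdmr", call_cdmr(tm, cases, controls,
                                    dmr_q = config$dmr_q,
                                    diff_thresh = config$diff_thresh,
                                    k_min = config$k_min,
                                    binom_q = config$cdmr_q,
                                    p0 = config$p0, n_perm = config$n_perm,
                                    perm_q = config$perm_q,
                                    seed = config$seed))
  data.table::fwrite(dmr_table(cd$batches[[1]], calls_only = TRUE),
                     file.path(out, "dmr_batch1_calls.tsv"), sep = "\t")
  data.table::fwrite(cd$results, file.path(out, "cdmr.tsv"), sep = "\t")
  stages <- c(stages, "cdmr")

  ent <- run_stage("entropy", {
    data.table::rbindlist(lapply(controls, function(ctrl) {
      et <- entropy_table(tm, cases, ctrl, input_kind = config$entropy_kind,
                          regions = cd$universe)
      et[, control_id := ctrl]
      et
    }))
  })
  data.table::fwrite(ent, file.path(out, "entropy.tsv"), sep = "\t")
  stages <- c(stages, "entropy")

  ctx <- run_stage("annotate", {
    feats <- gene_features(fx$genes)
    feats$cpg_island <- fx$tracks$cpg_island
    feats$`repeat` <- fx$tracks$`repeat`
    feats$enhancer <- fx$tracks$enhancer
    bg <- tm$regions[tm$regions$tile_id %in% cd$universe]
    res <- cd$results
    tabs <- lapply(c("hyper", "hypo"), function(d) {
      q <- res[res$direction == d & res$is_cdmr]
      if (!nrow(q)) return(NULL)
      ld <- location_distribution(q[, .(chrom, start, end)],
                                  bg[, .(chrom, start, end)], feats)
      ld[, direction := d]
      ld
    })
    data.table::rbindlist(tabs)
  })
  data.table::fwrite(ctx, file.path(out, "annotation.tsv"), sep = "\t")
  stages <- c(stages, "annotate")

  prof <- run_stage("profile", {
    if (is.null(fx$expression)) stop("expression input missing")
    feats <- gene_features(fx$genes)
    em <- rowMeans(fx$expression[, cases, drop = FALSE])
    quart <- assign_quartiles(em)
    data.table::rbindlist(lapply(levels(quart), function(qq) {
      p <- metagene_profile(fx$coverage, feats,
                            names(em)[quart == qq], unit = "gene",
                            sample_ids = cases)
      p[, quartile := qq]
      p
    }))
  })
  data.table::fwrite(prof, file.path(out, "profiles.tsv"), sep = "\t")
  stages <- c(stages, "profile")

  com <- run_stage("comodule", {
    if (is.null(fx$expression)) stop("expression input missing")
    feats <- gene_features(fx$genes)
    dm <- build_differential_matrices(fx$expression, fx$coverage, feats,
                                      cases, controls[1])
    mse <- detect_modules(dm$expr, beta = config$beta,
                          cut_height = config$cut_height,
                          min_size = min(config$min_size, nrow(dm$expr)))
    msm <- detect_modules(dm$meth, beta = config$beta,
                          cut_height = config$cut_height,
                          min_size = min(config$min_size, nrow(dm$meth)))
    res <- list(membership_expr = mse$membership,
                membership_meth = msm$membership)
    if (length(msm$modules) && length(mse$modules)) {
      res$overlap <- crosstab_overlap(msm, mse, rownames(dm$expr))
      res$preservation <- preservation_z(mse, dm$expr, dm$meth,
                                         beta = config$beta,
                                         n_perm = config$n_perm,
                                         seed = config$seed)
      res$eigengene_cor <- eigengene_correlation(msm, mse)
    }
    res
  })
  for (nm in names(com))
    data.table::fwrite(com[[nm]], file.path(out, paste0("comodule_", nm,
                                                        ".tsv")), sep = "\t")
  stages <- c(stages, "comodule")

  inputs <- list.files(config$fixture_dir, recursive = TRUE,
                       full.names = TRUE)
  manifest <- list(
    package = "conmeth",
    version = as.character(utils::packageVersion("conmeth")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("fixture_dir", "out",
                                                 "sim_config"))],
    stages = stages,
    input_checksums = as.list(tools::md5sum(inputs)))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(manifest)
}
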