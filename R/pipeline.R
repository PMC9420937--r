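# End-to-end orchestration of a synthetic breakome analysis.
#
# One flat YAML (or list) configuration drives every stage in dependency
# order: simulate -> hotspots -> tss -> enrich -> elements -> expression ->
# motif. All randomness flows from one root seed with fixed per-stage
# offsets, so reruns with an identical configuration are byte-identical.

.pipeline_stages <- c("simulate", "hotspots", "tss", "enrich", "elements",
                      "expression", "motif")

#' Run the breakome analysis pipeline
#'
#' @param config Path to a YAML file or a list. Recognised keys: `seed`
#'   (root seed, default 1), `stages` (subset of simulate/hotspots/tss/
#'   enrich/elements/expression/motif; default all), `simulate` (overrides
#'   for [sim_config()]), `hotspots` (`min_support`, `n_sim`), `enrich`
#'   (`inner`, `outer`), `expression` (`n_random`), `motif` (`flank`).
#' @param out_dir Output directory; created if missing.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, the run manifest (also written as `manifest.json`):
#'   config snapshot, derived seeds, per-stage output paths and md5
#'   checksums.
#' @export
run_pipeline <- function(config = list(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("`config` must be a list or a YAML path")
  stages <- config$stages %||% .pipeline_stages
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad) > 0) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  seed <- as.integer(config$seed %||% 1L)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- function(fmt, ...) {
    if (!quiet) message(sprintf("[breakome] %s", sprintf(fmt, ...)))
  }
  outputs <- list()
  t0 <- Sys.time()

  sim_args <- config$simulate %||% list()
  sim_args$seed <- seed
  cfg <- do.call(sim_config, sim_args)

  log("simulate: generating study (seed %d)", seed)
  study <- simulate_breakome_study(
    cfg, dir = if ("simulate" %in% stages) file.path(out_dir, "simulate") else NULL)
  if ("simulate" %in% stages) outputs$simulate <- unlist(study$files)
  genome <- study$genome
  pooled <- bind_rows(study$replicas)
  support <- build_support(pooled)

  if ("hotspots" %in% stages) {
    hs_cfg <- config$hotspots %||% list()
    min_support <- hs_cfg$min_support %||% 2L
    n_sim <- hs_cfg$n_sim %||% 100L
    log("hotspots: support >= %d, %d null simulations", min_support, n_sim)
    hotspots <- call_hotspots(support, min_support)
    frac <- hotspot_fraction(support, min_support)
    null <- simulate_null(
      n_replicas = cfg$n_replicas,
      breaks_per_replica = vapply(study$replicas, nrow, 1L),
      space_size = 2 * genome$lg, n_sim = n_sim,
      min_support = min_support, seed = seed + 101L)
    test <- hotspot_significance(frac, null)
    d <- file.path(out_dir, "hotspots")
    dir.create(d, showWarnings = FALSE)
    readr::write_tsv(support, file.path(d, "support.tsv"))
    write_positions(hotspots, file.path(d, "hotspots.bed"))
    readr::write_tsv(tibble(simulation = seq_along(null$fractions),
                            fraction = null$fractions),
                     file.path(d, "null.tsv"))
    readr::write_tsv(glance(test), file.path(d, "summary.tsv"))
    outputs$hotspots <- file.path(d, c("support.tsv", "hotspots.bed",
                                       "null.tsv", "summary.tsv"))
  } else {
    hotspots <- call_hotspots(support, 2L)
  }

  peaks <- call_cage_peaks(study$annotation$cage)
  tss <- assign_tss(study$annotation$genes, peaks)
  if ("tss" %in% stages) {
    log("tss: %d expressed genes", nrow(tss))
    d <- file.path(out_dir, "tss")
    dir.create(d, showWarnings = FALSE)
    readr::write_tsv(tss, file.path(d, "tss.tsv"))
    outputs$tss <- file.path(d, "tss.tsv")
  }

  if ("enrich" %in% stages) {
    en_cfg <- config$enrich %||% list()
    inner <- en_cfg$inner %||% 200
    outer <- en_cfg$outer %||% 5000
    log("enrich: density profile and enrichment ratios")
    grid <- build_bin_grid(tss, genome, window = outer)
    prof <- bind_rows(
      density_profile(pooled, tss, grid, sample_id = "all_breaks"),
      density_profile(hotspots, tss, grid, sample_id = "hotspots")
    )
    enr <- bind_rows(
      enrichment_ratio(pooled, tss, genome, inner, outer,
                       sample_id = "all_breaks"),
      enrichment_ratio(hotspots, tss, genome, inner, outer,
                       sample_id = "hotspots")
    )
    d <- file.path(out_dir, "enrich")
    dir.create(d, showWarnings = FALSE)
    readr::write_tsv(prof, file.path(d, "profile.tsv"))
    readr::write_tsv(enr, file.path(d, "enrichment.tsv"))
    outputs$enrich <- file.path(d, c("profile.tsv", "enrichment.tsv"))
  }

  if ("elements" %in% stages) {
    log("elements: hierarchical assignment and odds ratios")
    hier <- build_hierarchy(genome, study$annotation$genes, tss = tss,
                            cage_peaks = peaks,
                            promoters = study$annotation$promoters)
    dedup <- distinct(pooled, .data$chrom, .data$pos, .data$strand)
    elems <- bind_rows(
      mutate(element_enrichment(dedup, hier), sample = "all_breaks",
             .before = 1),
      mutate(element_enrichment(hotspots, hier), sample = "hotspots",
             .before = 1)
    )
    d <- file.path(out_dir, "elements")
    dir.create(d, showWarnings = FALSE)
    readr::write_tsv(elems, file.path(d, "elements.tsv"))
    outputs$elements <- file.path(d, "elements.tsv")
  }

  if ("expression" %in% stages) {
    ex_cfg <- config$expression %||% list()
    n_random <- ex_cfg$n_random %||% 1e5
    log("expression: strata odds ratios (%d random positions)", n_random)
    strata <- rank_strata(study$annotation$expression)
    expd <- expected_fractions(genome, tss, strata, n_random = n_random,
                               seed = seed + 202L)
    dedup <- distinct(pooled, .data$chrom, .data$pos, .data$strand)
    ors <- bind_rows(
      mutate(expression_odds_ratios(dedup, tss, strata, expd),
             sample = "all_breaks", .before = 1),
      mutate(expression_odds_ratios(hotspots, tss, strata, expd),
             sample = "hotspots", .before = 1)
    )
    d <- file.path(out_dir, "expression")
    dir.create(d, showWarnings = FALSE)
    readr::write_tsv(ors, file.path(d, "expr_or.tsv"))
    outputs$expression <- file.path(d, "expr_or.tsv")
  }

  if ("motif" %in% stages) {
    mo_cfg <- config$motif %||% list()
    flank <- mo_cfg$flank %||% 5
    log("motif: context matrices (flank %d)", flank)
    dedup <- distinct(pooled, .data$chrom, .data$pos, .data$strand)
    mats <- list(
      all_breaks = frequency_matrix(extract_contexts(dedup, genome, flank)),
      hotspots = frequency_matrix(extract_contexts(hotspots, genome, flank))
    )
    tab <- bind_rows(lapply(names(mats), function(nm) {
      mutate(as_tibble(mats[[nm]]), sample = nm, .before = 1)
    }))
    cg <- bind_rows(lapply(names(mats), function(nm) {
      mutate(cg_ratio(mats[[nm]]), sample = nm, .before = 1)
    }))
    d <- file.path(out_dir, "motif")
    dir.create(d, showWarnings = FALSE)
    readr::write_tsv(tab, file.path(d, "motif.tsv"))
    readr::write_tsv(cg, file.path(d, "cg_ratio.tsv"))
    outputs$motif <- file.path(d, c("motif.tsv", "cg_ratio.tsv"))
  }

  files <- unname(unlist(outputs))
  manifest <- list(
    package_version = as.character(utils::packageVersion("breakome")),
    seed = seed,
    derived_seeds = list(simulate = seed, null = seed + 101L,
                         random_breaks = seed + 202L),
    config = config[setdiff(names(config), "stages")],
    stages = as.list(stages),
    outputs = lapply(outputs, as.list),
    checksums = as.list(tools::md5sum(files)),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log("done in %.1f s", manifest$elapsed_seconds)
  invisible(manifest)
}
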