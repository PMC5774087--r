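# End-to-end orchestration: simulate (or read) observations, call mosaics,
# filter lines, build and screen the bin map, impute, estimate the genetic
# map, scan traits, and write every artifact with provenance.

#' Run the full bin-mapping and QTL pipeline
#'
#' Stages: (1) simulate a RIL population (or read observations from
#' `config$input$observations`), (2) sliding-window genotype calling and
#' block filtering, (3) line filtering, (4) bin construction,
#' (5) segregation-distortion screen and distorted-bin discard,
#' (6) heterozygote-to-missing imputation, (7) genetic map, (8) QTL scan of
#' each phenotype (simulated or read from `config$input$phenotypes`).
#' All artifacts are written under `out_dir` together with a provenance
#' JSON recording the seed, thresholds and per-stage record counts.
#'
#' @param config nested list (or path to a YAML/JSON file) with optional
#'   sections `simulation` (arguments of [sim_params()] plus `layout`
#'   arguments `n_chrom`, `length_bp`, `length_cM`, `n_snps`), `caller`
#'   (arguments of [caller_config()]), `scan` (arguments of
#'   [scan_config()]), `qtl` (data.frame chrom, pos, effect for planted
#'   QTLs), `input` (paths `observations`, `phenotypes`), `seed`.
#' @param out_dir artifact directory (created).
#' @return invisible list with all stage objects (`sim`, `mosaics`,
#'   `retained`, `excluded`, `binmap`, `distortion`, `genmap`, `scans`,
#'   `provenance`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  log_msg <- function(...) message("[binqtl] ", ...)

  sim_args <- config$simulation %||% list()
  lay_args <- sim_args[intersect(names(sim_args),
                                 c("n_chrom", "length_bp", "length_cM",
                                   "n_snps"))]
  par_args <- sim_args[intersect(names(sim_args),
                                 c("n_lines", "n_selfing_generations",
                                   "site_sampling_rate", "error_rate_p1",
                                   "error_rate_p2"))]
  caller <- do.call(caller_config, config$caller %||% list())
  scan_cfg <- do.call(scan_config,
                      utils::modifyList(list(seed = seed),
                                        config$scan %||% list()))

  sim <- NULL
  if (!is.null(config$input$observations)) {
    log_msg("stage read: ", config$input$observations)
    obs <- read_genotype_observations(config$input$observations)
    chrs <- unique(obs$chrom)
    layout <- config$layout %||% stop("explicit layout required with ",
                                      "external observations")
  } else {
    log_msg("stage simulate")
    layout <- do.call(uniform_layout, lay_args)
    params <- do.call(sim_params, c(par_args, list(seed = seed)))
    sim <- simulate_population(layout, params)
    obs <- sim$observations
    write_genotype_tsv(obs, file.path(out_dir, "observations.tsv"))
    write_mosaics_bed(
      data.frame(line = sim$mosaics$line, chrom = sim$mosaics$chrom,
                 start = sim$mosaics$start, end = sim$mosaics$end,
                 genotype = sim$mosaics$genotype, snp_count = NA),
      file.path(out_dir, "truth_mosaics.bed"))
  }

  log_msg("stage call: ", length(unique(obs$line)), " lines")
  mosaics <- call_mosaics(obs, layout, caller)
  fl <- filter_lines(mosaics, caller)
  log_msg("stage filter_lines: ", length(fl$retained), " retained, ",
          nrow(fl$excluded), " excluded")
  write_mosaics_bed(fl$mosaics$blocks, file.path(out_dir, "mosaics.bed"))
  if (length(fl$retained) < 2) {
    prov <- list(package = "binqtl",
                 version = as.character(utils::packageVersion("binqtl")),
                 seed = seed, n_lines_retained = length(fl$retained),
                 note = "fewer than 2 lines retained; no map built")
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    log_msg("fewer than 2 retained lines; stopping after line filter")
    return(invisible(list(sim = sim, mosaics = mosaics,
                          retained = fl$retained, excluded = fl$excluded,
                          binmap = NULL, genmap = NULL, scans = list(),
                          provenance = prov)))
  }

  log_msg("stage binmap")
  binmap <- construct_bins(fl$mosaics, layout)
  distortion <- test_segregation_distortion(binmap)
  binmap2 <- filter_distorted_bins(binmap)
  discarded <- attr(binmap2, "discarded_fraction")
  log_msg("stage distortion: ", sum(distortion$distorted),
          " distorted bins; ", round(100 * discarded, 1),
          "% discarded by ratio/het rule")
  imputed <- impute_genotypes(binmap2)
  genmap <- build_genetic_map(imputed)
  write_bin_map(imputed, file.path(out_dir, "binmap"))
  write_genetic_map(genmap, file.path(out_dir, "genetic_map.tsv"))
  data.table::fwrite(distortion, file.path(out_dir, "distortion.tsv"),
                     sep = "\t")
  data.table::fwrite(genmap$summary, file.path(out_dir, "map_summary.tsv"),
                     sep = "\t")

  # phenotypes: external file, or simulated from config$qtl
  phen <- NULL
  if (!is.null(config$input$phenotypes)) {
    phen <- read_phenotypes_tsv(config$input$phenotypes)
  } else if (!is.null(sim)) {
    qtl <- config$qtl
    if (is.null(qtl)) {
      chr1 <- layout$chromosomes$name[1]
      qtl <- data.frame(chrom = chr1,
                        pos = round(layout$chromosomes$length_bp[1] / 2),
                        effect = 1)
    } else qtl <- as.data.frame(qtl)
    phen <- simulate_phenotypes(sim, qtl,
                                env_effects = c(0, 0),
                                residual_sd = config$residual_sd %||% 2,
                                seed = seed + 1000L)
    write_phenotypes_tsv(phen, file.path(out_dir, "phenotypes.tsv"))
  }

  scans <- list()
  if (!is.null(phen)) {
    blup <- blup_line_values(phen)
    for (tr in unique(blup$blups$trait)) {
      log_msg("stage scan: ", tr)
      b <- blup$blups[blup$blups$trait == tr, ]
      y <- stats::setNames(b$blup, b$line)
      res <- scan_qtl(imputed, genmap, y, trait = tr, cfg = scan_cfg)
      scans[[tr]] <- res
      data.table::fwrite(res$lod,
                         file.path(out_dir, paste0("lod_", tr, ".tsv")),
                         sep = "\t")
      pk <- res$peaks
      if (nrow(pk)) {
        pk$peak_Mb <- pk$peak_bp / 1e6
        pk$interval_start_Mb <- pk$interval_start_bp / 1e6
        pk$interval_end_Mb <- pk$interval_end_bp / 1e6
        pk$trait <- tr
      }
      data.table::fwrite(pk, file.path(out_dir, paste0("qtl_", tr, ".tsv")),
                         sep = "\t")
      log_msg("  threshold ", round(res$threshold, 2), "; ",
              nrow(pk), " peak(s)")
    }
  }

  prov <- list(
    package = "binqtl",
    version = as.character(utils::packageVersion("binqtl")),
    seed = seed,
    caller = unclass(caller),
    scan = unclass(scan_cfg),
    n_lines_input = length(unique(obs$line)),
    n_lines_retained = length(fl$retained),
    n_lines_excluded = nrow(fl$excluded),
    n_bins = ncol(binmap$geno),
    n_bins_after_distortion_filter = ncol(binmap2$geno),
    distorted_bin_fraction = mean(distortion$distorted),
    discarded_bin_fraction = discarded,
    total_cM = sum(genmap$summary$total_cM),
    total_crossovers = count_crossovers(imputed)$total,
    n_peaks = vapply(scans, function(s) nrow(s$peaks), numeric(1)))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, mosaics = mosaics, retained = fl$retained,
                 excluded = fl$excluded, binmap = imputed,
                 distortion = distortion, genmap = genmap, scans = scans,
                 provenance = prov))
}

#' Read a pipeline configuration file
#'
#' @param path YAML (or JSON) configuration file mirroring the nested list
#'   accepted by [run_pipeline()].
#' @return nested list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}
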