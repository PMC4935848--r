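run_config_defaults <- function() {
  list(
    seed = 1L,
    population = list(n_variants = 200L, maf_low = 0.01, maf_high = 0.05,
                      x_fraction = 0.04),
    disease = list(prevalence = 0.05, causal_index = 1L, causal_af = 0.02,
                   grr_het = 3, grr_hom = 9),
    cohorts = list(n_genotyped_cases = 1300L, n_genotyped_controls = 700L,
                   n_reference = 6000L, reference_male_fraction = 0.43,
                   round1_cases = 180L, round1_controls = 180L),
    sim = list(pool_size = 10L, n_pools = 10L, mean_depth = 220,
               depth_dispersion = 0.05, representation_concentration = Inf,
               error_rate = 0.001, missing_rate = 0.02,
               genotyping_error_rate = 0.001),
    panels = list(drift_sd = 0.05),
    filter = list(min_pe_pools = 2, tc_high_cut = 5, tc_low_cut = 2,
                  freq_maf_max = 0.05, enrichment_ratio_min = 1.5,
                  low_mapq_fraction = 0.03, suspected_fraction = 0.02),
    association = list(hwe_alpha = 0.05, or_low = 0.65, or_high = 1.3,
                       max_missing = 2),
    traits = list(trait_name = "sbp_highest", beta_per_allele = 0.5,
                  noise_sd = 1, intercept = 0),
    power = list(alpha = 5e-8, target_power = 0.8)
  )
}

#' Build and validate a full pipeline run configuration
#'
#' Nested sections `population`, `disease`, `cohorts`, `sim`, `panels`,
#' `filter`, `association`, `traits`, `power` plus a master `seed`. Unknown
#' keys are rejected; cross-section constraints (enough cases to fill the
#' pools, valid rates) are checked up front so an invalid configuration
#' fails before any stage runs. Round-trips losslessly through JSON via
#' [write_run_config()] / [read_run_config()].
#'
#' @param ... named sections (lists) or `seed`, overriding the defaults.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  cfg <- run_config_defaults()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (nm in names(user)) {
    if (nm == "seed") { cfg$seed <- user$seed; next }
    sub_bad <- setdiff(names(user[[nm]]), names(cfg[[nm]]))
    if (length(sub_bad))
      stop("unknown key(s) in section '", nm, "': ",
           paste(sub_bad, collapse = ", "))
    cfg[[nm]][names(user[[nm]])] <- user[[nm]]
  }
  with(cfg, {
    if (sim$pool_size * sim$n_pools > cohorts$n_genotyped_cases)
      stop("pool design needs ", sim$pool_size * sim$n_pools,
           " cases but only ", cohorts$n_genotyped_cases, " are configured")
    stopifnot(population$maf_low <= population$maf_high,
              disease$prevalence > 0, disease$prevalence < 1,
              cohorts$round1_cases <= cohorts$n_genotyped_cases,
              cohorts$round1_controls <= cohorts$n_genotyped_controls)
  })
  # exercises the rate checks
  do.call(sim_config, c(cfg$sim, list(n_cases = cfg$cohorts$n_genotyped_cases,
                                      n_reference = cfg$cohorts$n_reference)))
  structure(cfg, class = "run_config")
}

#' Serialise / deserialise a run configuration as JSON
#' @param cfg a [run_config()].
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$sim$representation_concentration) &&
      is.character(raw$sim$representation_concentration))
    raw$sim$representation_concentration <- Inf  # JSON has no Inf literal
  do.call(run_config, raw)
}

#' Execute the full screen: simulate, pool, filter, validate, associate
#'
#' Runs every stage of the emulated study design in order, writing each
#' stage's outputs under `out_dir` and a `manifest.json` recording the seed,
#' package version and per-stage record counts. Reruns with the same
#' configuration are byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) the output directory; side effect: files written.
#' @export
run_screen <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  manifest <- list(package = "poolscreen",
                   version = as.character(utils::packageVersion("poolscreen")),
                   seed = config$seed, counts = list(), files = character())
  note <- function(stage, n, files = character()) {
    manifest$counts[[stage]] <<- n
    manifest$files <<- c(manifest$files, files)
  }
  seed_of <- function(stage) stage_seed(config$seed, stage)

  # 1. variant universe
  pop <- simulate_population(config$population$n_variants,
                             config$population$maf_low,
                             config$population$maf_high,
                             seed = seed_of("population"),
                             x_fraction = config$population$x_fraction)
  ci <- config$disease$causal_index
  causal_id <- NULL
  if (!is.null(ci) && !is.na(ci) && nrow(pop) >= ci && ci >= 1) {
    causal_id <- pop$id[ci]
    pop$func[ci] <- "missense"     # the planted causal must be codable
    pop$chrom[ci] <- "2"           # keep it autosomal for the merged analysis
    if (!is.null(config$disease$causal_af))
      pop$af[ci] <- config$disease$causal_af
  }
  write_variants_vcf(pop, pth("population.vcf"))
  note("population", nrow(pop), "population.vcf")
  dis <- disease_model(config$disease$prevalence, causal_id,
                       config$disease$grr_het, config$disease$grr_hom)

  # 2. case-control cohort (cases include the pooled subset)
  cohort <- solve_and_sample_cohort(pop, dis,
                                    config$cohorts$n_genotyped_cases,
                                    config$cohorts$n_genotyped_controls,
                                    selected_controls = TRUE,
                                    seed = seed_of("cohort"))
  cohort <- simulate_quantitative_traits(
    cohort, causal = if (is.null(causal_id)) pop$id[1] else causal_id,
    beta_per_allele = if (is.null(causal_id)) 0 else config$traits$beta_per_allele,
    noise_sd = config$traits$noise_sd,
    trait_name = config$traits$trait_name,
    intercept = config$traits$intercept, seed = seed_of("traits"))
  note("cohort", nrow(cohort$samples))

  # 3. pooling and pooled sequencing
  scfg <- do.call(sim_config, c(config$sim,
                                list(n_cases = config$cohorts$n_genotyped_cases,
                                     n_reference = config$cohorts$n_reference)))
  pools <- build_pools(cohort, scfg$pool_size, scfg$n_pools,
                       seed = seed_of("pools"))
  utils::write.table(pools, pth("pools.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  reads <- simulate_pooled_reads(pools, cohort, scfg, seed = seed_of("reads"))
  write_pool_counts(reads, pth("pooled_counts.tsv"))
  note("pooled_reads", nrow(reads$ref), c("pools.tsv", "pooled_counts.tsv"))

  # 4. reference panels
  panels <- simulate_reference_panels(pop, config$panels$drift_sd,
                                      config$cohorts$n_reference,
                                      config$cohorts$reference_male_fraction,
                                      scfg, seed = seed_of("panels"))
  write_panel(panels$cohort, pth("panel_cohort.tsv"))
  write_panel(panels$freq, pth("panel_freq.tsv"))
  note("panels", 3L, c("panel_cohort.tsv", "panel_freq.tsv"))

  # 5. per-variant summary table for the cascade
  set.seed(seed_of("annotation"))
  vt <- summarize_pooled_reads(reads)
  vt <- merge(pop, vt, by = "id", sort = FALSE)
  vt$mapq <- ifelse(stats::runif(nrow(vt)) < config$filter$low_mapq_fraction,
                    sample(5:19, nrow(vt), replace = TRUE), 60L)
  vt$suspected <- stats::runif(nrow(vt)) < config$filter$suspected_fraction
  if (!is.null(causal_id)) {
    # the planted signal is a clean call; artefact labels go elsewhere
    vt$mapq[vt$id == causal_id] <- 60L
    vt$suspected[vt$id == causal_id] <- FALSE
  }
  vt$cohort_af <- panels$cohort$counts$af[match(vt$id,
                                                panels$cohort$counts$variant_id)]
  vt$freq_af <- panels$freq$af[match(vt$id, panels$freq$variant_id)]
  vt$tc_af <- panels$pooled$af[vt$id]
  vt$tc_pools <- panels$pooled$pools_present[vt$id]
  vt$tc_pools_ref <- panels$pooled$pools_present_ref[vt$id]
  vt$alt_source_af <- NA_real_
  fam_pool <- colnames(reads$ref)[1]  # by convention the family pool is pool01
  pres <- call_pool_presence(reads$ref, reads$alt)
  vt$family_pool <- pres[vt$id, fam_pool]
  vt <- orient_minor_allele(vt)
  utils::write.table(vt, pth("variant_table.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("variant_table", nrow(vt), "variant_table.tsv")

  # 6. filter cascade
  fcfg <- filter_config(min_pe_pools = config$filter$min_pe_pools,
                        tc_high_cut = config$filter$tc_high_cut,
                        tc_low_cut = config$filter$tc_low_cut,
                        freq_maf_max = config$filter$freq_maf_max,
                        enrichment_ratio_min = config$filter$enrichment_ratio_min)
  casc <- run_cascade(vt, fcfg)
  utils::write.table(casc$candidates, pth("candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(casc$audit, pth("cascade_audit.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(casc$stage_counts), pth("stage_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  note("candidates", nrow(casc$candidates),
       c("candidates.tsv", "cascade_audit.tsv", "stage_counts.json"))
  cand_ids <- casc$candidates$id

  # 7. round-1 genotype validation in a small case-control set
  r1_ids <- c(cohort$samples$sample_id[cohort$samples$status == 1L][
                seq_len(config$cohorts$round1_cases)],
              cohort$samples$sample_id[cohort$samples$status == 0L][
                seq_len(config$cohorts$round1_controls)])
  r1 <- subset_dataset(cohort, r1_ids, cand_ids)
  r1_obs <- simulate_genotyping(r1, scfg$missing_rate,
                                scfg$genotyping_error_rate, n_runs = 1,
                                seed = seed_of("round1"))[[1]]
  r1_assoc <- associate_cc(r1_obs, r1$samples$status,
                           hwe_alpha = config$association$hwe_alpha)
  utils::write.table(r1_assoc, pth("round1_assoc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  r2_sel <- select_round2(r1_assoc, config$association$or_low,
                          config$association$or_high,
                          config$association$hwe_alpha)
  note("round1", nrow(r1_assoc), "round1_assoc.tsv")
  r2_ids <- r2_sel$variant_id
  note("round2_selected", length(r2_ids))

  # 8. round-2 genotyping, concordance, sample QC, association
  r2 <- subset_dataset(cohort, cohort$samples$sample_id, r2_ids)
  r2_obs <- simulate_genotyping(r2, scfg$missing_rate,
                                scfg$genotyping_error_rate, n_runs = 1,
                                seed = seed_of("round2"))[[1]]
  # duplicate observation of the round-1 participants for concordance
  dup_obs <- simulate_genotyping(subset_dataset(cohort, r1_ids, r2_ids),
                                 scfg$missing_rate,
                                 scfg$genotyping_error_rate, n_runs = 1,
                                 seed = seed_of("round2dup"))[[1]]
  conc <- if (length(r2_ids))
    concordance_check(r2_obs[r1_ids, , drop = FALSE], dup_obs)
  else list(rate = NA_real_, excluded_samples = character())
  qc <- sample_qc(r2_obs, config$association$max_missing,
                  r2$samples$status)
  keep <- setdiff(qc$kept, conc$excluded_samples)
  r2_obs <- r2_obs[keep, , drop = FALSE]
  r2_status <- r2$samples$status[match(keep, r2$samples$sample_id)]
  r2_assoc <- if (length(r2_ids))
    associate_cc(r2_obs, r2_status, config$association$hwe_alpha,
                 chrom = r2$variants$chrom[match(colnames(r2_obs),
                                                 r2$variants$id)])
  else NULL
  if (!is.null(r2_assoc))
    utils::write.table(r2_assoc, pth("round2_assoc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  note("round2", if (is.null(r2_assoc)) 0L else nrow(r2_assoc),
       if (is.null(r2_assoc)) character() else "round2_assoc.tsv")

  # 9. merged analysis against the population reference
  merged_assoc <- NULL
  if (length(r2_ids)) {
    ok_hwe <- r2_assoc$variant_id[!r2_assoc$hwe_fail]
    cnt <- genotype_counts(r2_obs[, ok_hwe, drop = FALSE], r2_status)
    ctl <- cnt[cnt$group == "control", ]
    ctl$chrom <- r2$variants$chrom[match(ctl$variant_id, r2$variants$id)]
    ref <- panels$cohort$counts[panels$cohort$counts$variant_id %in% ok_hwe, ]
    mg <- merge_reference(ctl, ref, mixed_sex_reference = TRUE)
    cas <- cnt[cnt$group == "case", ]
    merged_assoc <- associate_counts(cas, mg$merged,
                                     config$association$hwe_alpha)
    if (!is.null(merged_assoc)) {
      merged_assoc$x_excluded <- FALSE
      if (length(mg$x_excluded))
        merged_assoc <- rbind(merged_assoc,
          data.frame(variant_id = mg$x_excluded, case_maf = NA, control_maf = NA,
                     chi2 = NA, p = NA, or = NA, ci_low = NA, ci_high = NA,
                     hwe_p_case = NA, hwe_p_control = NA, monomorphic = FALSE,
                     hwe_fail = FALSE, x_excluded = TRUE,
                     stringsAsFactors = FALSE))
      utils::write.table(merged_assoc, pth("merged_assoc.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  note("merged", if (is.null(merged_assoc)) 0L else nrow(merged_assoc),
       if (is.null(merged_assoc)) character() else "merged_assoc.tsv")

  # 10. quantitative traits on the round-2 variants (cases only, additive)
  qtl <- NULL
  if (length(r2_ids)) {
    trait <- cohort$samples[[config$traits$trait_name]][
      match(keep, cohort$samples$sample_id)]
    qtl <- do.call(rbind, lapply(r2_ids, function(v) {
      fit <- quant_regression(r2_obs[r2_status == 1L, v],
                              trait[r2_status == 1L])
      data.frame(variant_id = v, trait = config$traits$trait_name,
                 beta = fit$beta, se = fit$se, t = fit$t, p = fit$p,
                 n = fit$n, stringsAsFactors = FALSE)
    }))
    utils::write.table(qtl, pth("qtl_assoc.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  note("qtl", if (is.null(qtl)) 0L else nrow(qtl),
       if (is.null(qtl)) character() else "qtl_assoc.tsv")

  # 11. design power summary
  pw <- allelic_power(config$disease$prevalence,
                      raf = if (is.null(causal_id)) config$population$maf_low
                            else pop$af[match(causal_id, pop$id)],
                      grr_het = config$disease$grr_het,
                      grr_hom = config$disease$grr_hom,
                      n_cases = config$cohorts$n_genotyped_cases,
                      n_controls = config$cohorts$n_genotyped_controls +
                        config$cohorts$n_reference,
                      alpha = config$power$alpha)
  jsonlite::write_json(list(power = pw$power, ncp = pw$ncp,
                            alpha = config$power$alpha,
                            concordance = conc$rate,
                            penetrances = as.list(pw$penetrances)),
                       pth("power_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  note("power", 1L, "power_summary.json")

  write_run_config(config, pth("config.json"))
  manifest$files <- c(manifest$files, "config.json")
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

subset_dataset <- function(dataset, sample_ids, variant_ids) {
  structure(list(
    samples = dataset$samples[match(sample_ids, dataset$samples$sample_id), ,
                              drop = FALSE],
    genotypes = dataset$genotypes[sample_ids, variant_ids, drop = FALSE],
    variants = dataset$variants[dataset$variants$id %in% variant_ids, ,
                                drop = FALSE]
  ), class = "genotype_dataset")
}

#' Summarise a completed run as a report document
#'
#' Collects the stage-count funnel, the merged association table (one row
#' per final candidate analysed) and the power summary into one list, also
#' written as `report.json` in the run directory.
#'
#' @param run_dir directory produced by [run_screen()].
#' @return list of class `screen_report` with `funnel`, `association`,
#'   `power`, `manifest`.
#' @export
make_report <- function(run_dir) {
  required <- c("manifest.json", "stage_counts.json", "power_summary.json")
  missing <- required[!file.exists(file.path(run_dir, required))]
  if (length(missing))
    stop("incomplete run; missing artifact(s): ",
         paste(missing, collapse = ", "))
  manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  funnel <- unlist(jsonlite::read_json(file.path(run_dir, "stage_counts.json"),
                                       simplifyVector = TRUE))
  assoc_path <- file.path(run_dir, "merged_assoc.tsv")
  association <- if (file.exists(assoc_path))
    utils::read.delim(assoc_path, stringsAsFactors = FALSE)
  else data.frame()
  power <- jsonlite::read_json(file.path(run_dir, "power_summary.json"),
                               simplifyVector = TRUE)
  report <- structure(list(funnel = funnel, association = association,
                           power = power, manifest = manifest),
                      class = "screen_report")
  jsonlite::write_json(list(funnel = as.list(funnel),
                            n_candidates_analysed = nrow(association),
                            power = power),
                       file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.screen_report <- function(x, ...) {
  cat("screen report (seed ", x$manifest$seed, ")\n", sep = "")
  for (nm in names(x$funnel)) cat(sprintf("  %-12s %6d\n", nm, x$funnel[[nm]]))
  cat(sprintf("analysed candidates: %d; design power %.3f\n",
              nrow(x$association), x$power$power))
  invisible(x)
}
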