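#' Configuration of the candidate-selection filter cascade
#'
#' Houses every threshold of the enrichment filtering design: functional
#' classes retained, pool-presence cuts for the case pools and the pooled
#' technical-control panel, the frequency-panel MAF ceiling, the enrichment
#' ratio, gene blacklists, the dbSNP "suspected" exclusion, manual
#' include/exclude lists, and linkage-peak regions.
#'
#' @param functional_classes classes kept by the functional filter.
#' @param min_pe_pools minimum number of case pools a variant must be present
#'   in (default 2, i.e. "at least two").
#' @param tc_high_cut exclude variants present in more than this many
#'   technical-control pools (default 5, i.e. "over five" = >= 6 excluded).
#' @param tc_low_cut variants present in fewer than this many
#'   technical-control pools (default 2, i.e. "less than two" = 0 or 1) must
#'   additionally satisfy the frequency-panel MAF ceiling.
#' @param freq_maf_max frequency-panel (e.g. European reference) MAF ceiling
#'   applied by the low technical-control branch and the linkage-peak
#'   strategy (default 0.05). Variants absent from the panel pass.
#' @param enrichment_ratio_min minimum case-MAF / reference-MAF ratio,
#'   required against every panel reporting the variant (default 1.5).
#' @param blacklist_genes character vector of excluded gene symbols (e.g.
#'   read from published artifact-gene lists with [read_gene_list()]).
#' @param exclude_suspected drop variants carrying the dbSNP "suspected"
#'   flag (default `TRUE`).
#' @param manual_include,manual_exclude explicit variant-id lists applied
#'   after the automated stages (the near-cut-off rescues of the original
#'   design are modelled as a manual include list).
#' @param linkage_regions data.frame `chrom`, `start`, `end` (1-based
#'   inclusive) enabling the linkage-peak strategy when non-empty.
#' @param min_alt_reads,min_alt_fraction pool-presence thresholds, see
#'   [call_pool_presence()].
#' @param min_mapq,min_depth upstream quality thresholds, see
#'   [apply_quality_filters()].
#' @return list of class `filter_config`.
#' @export
filter_config <- function(functional_classes = c("missense", "nonsense", "splice"),
                          min_pe_pools = 2, tc_high_cut = 5, tc_low_cut = 2,
                          freq_maf_max = 0.05, enrichment_ratio_min = 1.5,
                          blacklist_genes = character(),
                          exclude_suspected = TRUE,
                          manual_include = character(),
                          manual_exclude = character(),
                          linkage_regions = NULL,
                          min_alt_reads = 2, min_alt_fraction = 0.01,
                          min_mapq = 20, min_depth = 10) {
  stopifnot(all(functional_classes %in% FUNCTIONAL_CLASSES),
            min_pe_pools >= 0, tc_high_cut >= 0, tc_low_cut >= 0,
            freq_maf_max >= 0, freq_maf_max <= 1, enrichment_ratio_min >= 0,
            min_alt_reads >= 0, min_alt_fraction >= 0)
  if (!is.null(linkage_regions)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(linkage_regions)),
              all(linkage_regions$start <= linkage_regions$end))
  }
  structure(list(functional_classes = functional_classes,
                 min_pe_pools = min_pe_pools, tc_high_cut = tc_high_cut,
                 tc_low_cut = tc_low_cut, freq_maf_max = freq_maf_max,
                 enrichment_ratio_min = enrichment_ratio_min,
                 blacklist_genes = blacklist_genes,
                 exclude_suspected = exclude_suspected,
                 manual_include = manual_include,
                 manual_exclude = manual_exclude,
                 linkage_regions = linkage_regions,
                 min_alt_reads = min_alt_reads,
                 min_alt_fraction = min_alt_fraction,
                 min_mapq = min_mapq, min_depth = min_depth),
            class = "filter_config")
}

#' Read a one-gene-per-line blacklist file
#' @param path text file, one gene symbol per line; `#` comments allowed.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Keep only variants of the allowed functional classes
#'
#' @param variants variant summary table with a `func` column.
#' @param cfg a [filter_config()].
#' @return the surviving rows. Unknown class labels raise an error (strict
#'   vocabulary: `missense, nonsense, splice, synonymous, other`).
#' @export
filter_functional <- function(variants, cfg = filter_config()) {
  bad <- setdiff(unique(variants$func), FUNCTIONAL_CLASSES)
  if (length(bad))
    stop("unknown functional class label(s): ", paste(bad, collapse = ", "))
  variants[variants$func %in% cfg$functional_classes, , drop = FALSE]
}

#' Keep variants present in enough case pools
#' @inheritParams filter_functional
#' @return rows with `pe_pools >= cfg$min_pe_pools`.
#' @export
filter_pe_pools <- function(variants, cfg = filter_config()) {
  variants[variants$pe_pools >= cfg$min_pe_pools, , drop = FALSE]
}

#' Technical-control pool filter
#'
#' Variants present in more than `tc_high_cut` technical-control pools are
#' excluded as likely artefacts or common variation. Variants present in
#' fewer than `tc_low_cut` pools are additionally required to have a
#' frequency-panel MAF `<= freq_maf_max` (variants the panel does not report
#' pass this sub-filter). Variants in between pass the stage unconditionally;
#' the enrichment stage still applies downstream.
#'
#' @inheritParams filter_functional
#' @return the surviving rows (uses columns `tc_pools`, `freq_af`).
#' @export
filter_tc_pools <- function(variants, cfg = filter_config()) {
  keep <- tc_pools_keep(variants, cfg)
  variants[keep, , drop = FALSE]
}

tc_pools_keep <- function(variants, cfg) {
  high <- variants$tc_pools > cfg$tc_high_cut
  low <- variants$tc_pools < cfg$tc_low_cut
  freq_ok <- is.na(variants$freq_af) | variants$freq_af <= cfg$freq_maf_max
  !high & (!low | freq_ok)
}

#' Case/reference enrichment ratio
#'
#' `pe_maf / ref_maf`, with `+Inf` when the variant is absent from the
#' reference (`ref_maf = 0`, `pe_maf > 0`; passes any finite threshold) and
#' `NA` (undefined) when both frequencies are zero.
#'
#' @param pe_maf,ref_maf frequencies in [0,1] (vectorised).
#' @return the ratio, `Inf`, or `NA`.
#' @export
enrichment_ratio <- function(pe_maf, ref_maf) {
  stopifnot(all(pe_maf >= 0 & pe_maf <= 1, na.rm = TRUE),
            all(ref_maf >= 0 & ref_maf <= 1, na.rm = TRUE))
  out <- pe_maf / ref_maf
  out[ref_maf == 0 & pe_maf > 0] <- Inf
  out[ref_maf == 0 & pe_maf == 0] <- NA_real_
  out
}

#' Multi-panel enrichment filter
#'
#' Keeps variants whose enrichment ratio is at least
#' `cfg$enrichment_ratio_min` against *every* reference panel that reports
#' the variant (cohort, frequency-only and technical-control panels).
#' Variants reported by no panel pass here and are judged by
#' [filter_alt_sources()].
#'
#' @inheritParams filter_functional
#' @param panel_cols names of the panel frequency columns.
#' @return the surviving rows.
#' @export
filter_enrichment <- function(variants, cfg = filter_config(),
                              panel_cols = c("cohort_af", "freq_af", "tc_af")) {
  keep <- enrichment_keep(variants, cfg, panel_cols)
  variants[keep, , drop = FALSE]
}

enrichment_keep <- function(variants, cfg,
                            panel_cols = c("cohort_af", "freq_af", "tc_af")) {
  keep <- rep(TRUE, nrow(variants))
  for (col in panel_cols) {
    if (!col %in% names(variants)) next
    r <- enrichment_ratio(variants$pe_af, variants[[col]])
    avail <- !is.na(variants[[col]])
    # an undefined ratio (0/0) against an available panel cannot demonstrate
    # enrichment; treat as failing
    keep <- keep & (!avail | (!is.na(r) & r >= cfg$enrichment_ratio_min))
  }
  keep
}

#' Gene blacklist and dbSNP "suspected" flag filter
#' @inheritParams filter_functional
#' @return rows whose `gene` is in no blacklist and (when
#'   `cfg$exclude_suspected`) whose `suspected` flag is `FALSE`.
#' @export
filter_blacklists <- function(variants, cfg = filter_config()) {
  drop <- variants$gene %in% cfg$blacklist_genes
  if (cfg$exclude_suspected && "suspected" %in% names(variants))
    drop <- drop | isTRUE_vec(variants$suspected)
  variants[!drop, , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Alternative-source frequency check for panel-less variants
#'
#' Applies only to variants that no default reference panel reports. Such a
#' variant is excluded when an alternative frequency source shows a MAF
#' "higher than or similar to" the pooled case MAF, operationalised as
#' `pe_af / alt_source_af < cfg$enrichment_ratio_min`. Variants with no
#' alternative source either are kept and flagged `no_reference`.
#'
#' @inheritParams filter_functional
#' @return the surviving rows, with a logical `no_reference` column added.
#' @export
filter_alt_sources <- function(variants, cfg = filter_config()) {
  keep <- alt_sources_keep(variants, cfg)
  out <- variants[keep, , drop = FALSE]
  out$no_reference <- no_panel_mask(out) & is.na(out$alt_source_af)
  out
}

no_panel_mask <- function(variants,
                          panel_cols = c("cohort_af", "freq_af", "tc_af")) {
  mask <- rep(TRUE, nrow(variants))
  for (col in intersect(panel_cols, names(variants)))
    mask <- mask & is.na(variants[[col]])
  mask
}

alt_sources_keep <- function(variants, cfg) {
  no_panel <- no_panel_mask(variants)
  has_alt <- !is.na(variants$alt_source_af)
  r <- enrichment_ratio(variants$pe_af, variants$alt_source_af)
  fail <- no_panel & has_alt & (is.na(r) | r < cfg$enrichment_ratio_min)
  !fail
}

#' Linkage-peak auxiliary candidate strategy
#'
#' Keeps variants lying inside a configured linkage-peak region (1-based
#' inclusive) that are present in the family pool, have a frequency-panel
#' MAF `<= freq_maf_max` (absence passes), and show enrichment ratio
#' `>= enrichment_ratio_min` in every available comparison.
#'
#' @inheritParams filter_functional
#' @return the candidate rows (uses columns `chrom`, `pos`, `family_pool`).
#' @export
linkage_peak_strategy <- function(variants, cfg = filter_config()) {
  if (is.null(cfg$linkage_regions) || nrow(cfg$linkage_regions) == 0)
    return(variants[0, , drop = FALSE])
  keep <- linkage_keep(variants, cfg)
  variants[keep, , drop = FALSE]
}

linkage_keep <- function(variants, cfg) {
  reg <- cfg$linkage_regions
  in_region <- rep(FALSE, nrow(variants))
  for (k in seq_len(nrow(reg))) {
    in_region <- in_region | (variants$chrom == reg$chrom[k] &
                              variants$pos >= reg$start[k] &
                              variants$pos <= reg$end[k])
  }
  freq_ok <- is.na(variants$freq_af) | variants$freq_af <= cfg$freq_maf_max
  in_region & isTRUE_vec(variants$family_pool) & freq_ok &
    enrichment_keep(variants, cfg)
}

#' Reference-allele-minor auxiliary candidate strategy
#'
#' Looks for candidates among variants whose *reference* allele is the minor
#' one: functional class allowed, frequency-panel reference-allele frequency
#' `<= freq_maf_max`, reference-allele enrichment ratio
#' `>= enrichment_ratio_min` against both the cohort and technical-control
#' panels, reference allele present in at most 2 technical-control pools and
#' in more than two case pools. All four frequency sources must be available.
#'
#' @inheritParams filter_functional
#' @param max_tc_pools_ref,min_pe_pools_ref pool-presence cuts for the
#'   reference allele (defaults 2 and 3, i.e. "<= 2" and "over two").
#' @return the candidate rows.
#' @export
ref_allele_minor_strategy <- function(variants, cfg = filter_config(),
                                      max_tc_pools_ref = 2,
                                      min_pe_pools_ref = 3) {
  keep <- ref_minor_keep(variants, cfg, max_tc_pools_ref, min_pe_pools_ref)
  variants[keep, , drop = FALSE]
}

ref_minor_keep <- function(variants, cfg, max_tc_pools_ref = 2,
                           min_pe_pools_ref = 3) {
  pe_ref <- 1 - variants$pe_af
  r_cohort <- enrichment_ratio(pe_ref, 1 - variants$cohort_af)
  r_tc <- enrichment_ratio(pe_ref, 1 - variants$tc_af)
  ok <- variants$func %in% cfg$functional_classes &
    !is.na(variants$freq_af) & (1 - variants$freq_af) <= cfg$freq_maf_max &
    !is.na(r_cohort) & r_cohort >= cfg$enrichment_ratio_min &
    !is.na(r_tc) & r_tc >= cfg$enrichment_ratio_min &
    variants$tc_pools_ref <= max_tc_pools_ref &
    variants$pe_pools_ref >= min_pe_pools_ref
  ok[is.na(ok)] <- FALSE
  ok
}

#' Run the full candidate-selection cascade
#'
#' Executes the main cascade (quality, functional class, case-pool presence,
#' technical-control pools, multi-panel enrichment, blacklists,
#' alternative-source check), then unions the two auxiliary strategies
#' (linkage peak and reference-allele-minor) and the manual include list,
#' minus the manual exclude list. Every stage is a pure predicate; the run is
#' idempotent and every input variant is accounted for in the audit trail.
#'
#' @param variants per-variant summary table (see the vignette for the
#'   column contract).
#' @param cfg a [filter_config()].
#' @return list of class `cascade_result`: `candidates` (data.frame `id`,
#'   `strategy` in `{main, linkage_peak, ref_allele_minor, manual}`),
#'   `stage_counts` (named survivor counts along the main cascade), `audit`
#'   (data.frame `id`, `stage`, `reason`, `kept`), and `survivors` (the main
#'   cascade's final ids).
#' @export
run_cascade <- function(variants, cfg = filter_config()) {
  stopifnot(is.data.frame(variants))
  audit <- data.frame(id = character(), stage = character(),
                      reason = character(), stringsAsFactors = FALSE)
  note_removed <- function(before, after, stage, reason = stage) {
    gone <- setdiff(before$id, after$id)
    if (length(gone))
      audit <<- rbind(audit, data.frame(id = gone, stage = stage,
                                        reason = reason,
                                        stringsAsFactors = FALSE))
    after
  }
  stage_counts <- c(input = nrow(variants))
  cur <- variants

  if (all(c("mapq", "max_depth") %in% names(variants)) && nrow(cur) > 0) {
    qc <- apply_quality_filters(cur, min_mapq = cfg$min_mapq,
                                min_depth = cfg$min_depth)
    if (nrow(qc$removed))
      audit <- rbind(audit, data.frame(id = qc$removed$id, stage = "quality",
                                       reason = qc$removed$reason,
                                       stringsAsFactors = FALSE))
    cur <- qc$kept
    stage_counts <- c(stage_counts, quality = nrow(cur))
  }
  after_quality <- cur

  cur <- note_removed(cur, filter_functional(cur, cfg), "functional")
  stage_counts <- c(stage_counts, functional = nrow(cur))
  cur <- note_removed(cur, filter_pe_pools(cur, cfg), "pe_pools")
  stage_counts <- c(stage_counts, pe_pools = nrow(cur))
  cur <- note_removed(cur, filter_tc_pools(cur, cfg), "tc_pools")
  stage_counts <- c(stage_counts, tc_pools = nrow(cur))
  cur <- note_removed(cur, filter_enrichment(cur, cfg), "enrichment")
  stage_counts <- c(stage_counts, enrichment = nrow(cur))
  cur <- note_removed(cur, filter_blacklists(cur, cfg), "blacklist")
  stage_counts <- c(stage_counts, blacklist = nrow(cur))
  cur <- note_removed(cur, filter_alt_sources(cur, cfg), "alt_sources")
  stage_counts <- c(stage_counts, alt_sources = nrow(cur))

  main_ids <- cur$id
  lp_ids <- linkage_peak_strategy(after_quality, cfg)$id
  rm_ids <- ref_allele_minor_strategy(after_quality, cfg)$id
  manual_ids <- intersect(cfg$manual_include, variants$id)

  strategy <- c(stats::setNames(rep("main", length(main_ids)), main_ids))
  for (id in setdiff(lp_ids, names(strategy))) strategy[id] <- "linkage_peak"
  for (id in setdiff(rm_ids, names(strategy))) strategy[id] <- "ref_allele_minor"
  for (id in setdiff(manual_ids, names(strategy))) strategy[id] <- "manual"
  excluded <- intersect(names(strategy), cfg$manual_exclude)
  if (length(excluded)) {
    audit <- rbind(audit, data.frame(id = excluded, stage = "manual_exclude",
                                     reason = "manual_exclude",
                                     stringsAsFactors = FALSE))
    strategy <- strategy[setdiff(names(strategy), excluded)]
  }
  candidates <- data.frame(id = names(strategy),
                           strategy = unname(strategy),
                           stringsAsFactors = FALSE)
  candidates <- candidates[order(match(candidates$id, variants$id)), ,
                           drop = FALSE]
  rownames(candidates) <- NULL
  stage_counts <- c(stage_counts, candidates = nrow(candidates))

  audit_full <- data.frame(id = variants$id,
                           stage = rep("final", nrow(variants)),
                           reason = rep("kept", nrow(variants)),
                           kept = variants$id %in% candidates$id,
                           stringsAsFactors = FALSE)
  drop_row <- match(audit_full$id, audit$id)
  has <- !is.na(drop_row)
  audit_full$stage[has] <- audit$stage[drop_row[has]]
  audit_full$reason[has] <- audit$reason[drop_row[has]]
  structure(list(candidates = candidates, stage_counts = stage_counts,
                 audit = audit_full, survivors = main_ids),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("filter cascade funnel:\n")
  for (nm in names(x$stage_counts))
    cat(sprintf("  %-12s %6d\n", nm, x$stage_counts[[nm]]))
  tab <- table(x$candidates$strategy)
  if (length(tab))
    cat("candidates by strategy:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
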