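#' Per-pool minor-allele frequency estimate from read counts
#'
#' The pooled estimator: the proportion of reads carrying the (putative
#' minor) alt allele among all reads covering the position in one pool. It is
#' unbiased for the pool allele fraction when every sample contributes reads
#' equally; [orient_minor_allele()] handles variants whose reference allele
#' is actually the minor one.
#'
#' @param ref_reads,alt_reads non-negative read counts (vectorised).
#' @return alt-read proportion in [0,1]; `NA` where the depth is zero (an
#'   undefined value, deliberately not 0).
#' @export
estimate_pool_maf <- function(ref_reads, alt_reads) {
  stopifnot(all(ref_reads >= 0, na.rm = TRUE), all(alt_reads >= 0, na.rm = TRUE))
  total <- ref_reads + alt_reads
  ifelse(total > 0, alt_reads / total, NA_real_)
}

#' Overall pooled minor-allele frequency across pools
#'
#' Read-weighted estimate over covered pools: total alt reads divided by the
#' total reads, i.e. `sum(alt) / sum(ref + alt)` over pools with positive
#' depth. Pools without coverage contribute nothing; with a single covered
#' pool this equals [estimate_pool_maf()].
#'
#' @param ref_reads,alt_reads per-pool read counts.
#' @return the overall alt-read proportion; `NA` when no pool is covered.
#' @export
estimate_overall_maf <- function(ref_reads, alt_reads) {
  stopifnot(length(ref_reads) == length(alt_reads),
            all(ref_reads >= 0, na.rm = TRUE), all(alt_reads >= 0, na.rm = TRUE))
  total <- sum(ref_reads) + sum(alt_reads)
  if (is.na(total) || total == 0) return(NA_real_)
  sum(alt_reads) / total
}

#' Call whether a variant is present in a pool
#'
#' A variant is called present in a pool when the alt allele is supported by
#' at least `min_alt_reads` reads *and* at least a fraction
#' `min_alt_fraction` of the pool's reads. The thresholds are explicit
#' stand-ins for a caller-dependent notion of presence and are configurable.
#'
#' @param ref_reads,alt_reads read counts (vectorised; matrices allowed).
#' @param min_alt_reads minimum supporting reads (default 2).
#' @param min_alt_fraction minimum supporting read fraction (default 0.01).
#' @return logical, same shape as the inputs; zero-depth pools are `FALSE`.
#' @export
call_pool_presence <- function(ref_reads, alt_reads, min_alt_reads = 2,
                               min_alt_fraction = 0.01) {
  stopifnot(min_alt_reads >= 0, min_alt_fraction >= 0)
  total <- ref_reads + alt_reads
  frac <- ifelse(total > 0, alt_reads / total, 0)
  out <- alt_reads >= min_alt_reads & frac >= min_alt_fraction
  out[is.na(out)] <- FALSE
  out
}

#' Mapping-quality and depth filters on pooled variants
#'
#' Keeps variants with mapping quality `>= min_mapq` and a total depth of at
#' least `min_depth` in at least one pool, recording the removal reason for
#' every dropped variant.
#'
#' @param variants data.frame with at least `id` and `mapq`; depth is taken
#'   from a `max_depth` column, or computed from `reads` when supplied.
#' @param reads optional `pooled_reads` object for the same variants.
#' @param min_mapq,min_depth thresholds (defaults 20 and 10).
#' @return list with `kept` (the surviving rows) and `removed`
#'   (data.frame `id`, `reason` in `{"mapq", "depth"}`).
#' @export
apply_quality_filters <- function(variants, reads = NULL, min_mapq = 20,
                                  min_depth = 10) {
  if (nrow(variants) == 0)
    return(list(kept = variants,
                removed = data.frame(id = character(), reason = character(),
                                     stringsAsFactors = FALSE)))
  if (!is.null(reads)) {
    depth <- reads$ref + reads$alt
    variants$max_depth <- apply(depth[variants$id, , drop = FALSE], 1, max)
  }
  stopifnot(all(c("id", "mapq", "max_depth") %in% names(variants)))
  bad_mapq <- variants$mapq < min_mapq
  bad_depth <- !bad_mapq & variants$max_depth < min_depth
  removed <- data.frame(
    id = variants$id[bad_mapq | bad_depth],
    reason = c("mapq", "depth")[1 + bad_depth[bad_mapq | bad_depth]],
    stringsAsFactors = FALSE)
  list(kept = variants[!(bad_mapq | bad_depth), , drop = FALSE],
       removed = removed)
}

#' Designate the minor allele of each variant
#'
#' The minor allele is the one with frequency `<= 0.5` in the primary
#' reference panel; when the panel does not report the variant the pooled
#' estimate is used as fallback. Ties at exactly 0.5 break toward the alt
#' allele. The orientation is recorded in a `minor_allele` column so the
#' reference-allele-minor candidate strategy can query it.
#'
#' @param variants data.frame with an alt-allele frequency column per source.
#' @param primary name of the primary panel frequency column (alt-allele
#'   frequency; default `"cohort_af"`).
#' @param fallback name of the fallback column (default `"pe_af"`, the pooled
#'   estimate).
#' @return `variants` with a `minor_allele` column in `{"alt", "ref"}`.
#' @export
orient_minor_allele <- function(variants, primary = "cohort_af",
                                fallback = "pe_af") {
  stopifnot(primary %in% names(variants))
  af <- variants[[primary]]
  if (fallback %in% names(variants)) {
    use_fb <- is.na(af)
    af[use_fb] <- variants[[fallback]][use_fb]
  }
  if (anyNA(af))
    stop("no frequency source available for variants: ",
         paste(utils::head(variants$id[is.na(af)], 5), collapse = ", "))
  variants$minor_allele <- ifelse(af > 0.5, "ref", "alt")
  variants
}

#' Summarise pooled read counts into a per-variant estimates table
#'
#' Convenience assembly used by the pipeline: per-pool MAFs, the overall
#' read-weighted MAF, presence counts for both alleles, and maximum depth.
#'
#' @param reads a `pooled_reads` object.
#' @param min_alt_reads,min_alt_fraction presence thresholds, see
#'   [call_pool_presence()].
#' @return data.frame keyed by `id` with `pe_af`, `pe_pools`, `pe_pools_ref`,
#'   `max_depth` and one `maf_<pool>` column per pool.
#' @export
summarize_pooled_reads <- function(reads, min_alt_reads = 2,
                                   min_alt_fraction = 0.01) {
  stopifnot(inherits(reads, "pooled_reads"))
  per_pool <- reads$alt / pmax(1L, reads$ref + reads$alt)
  per_pool[reads$ref + reads$alt == 0] <- NA_real_
  pres_alt <- call_pool_presence(reads$ref, reads$alt, min_alt_reads,
                                 min_alt_fraction)
  pres_ref <- call_pool_presence(reads$alt, reads$ref, min_alt_reads,
                                 min_alt_fraction)
  out <- data.frame(
    id = rownames(reads$ref),
    pe_af = vapply(seq_len(nrow(reads$ref)), function(v)
      estimate_overall_maf(reads$ref[v, ], reads$alt[v, ]), numeric(1)),
    pe_pools = rowSums(pres_alt),
    pe_pools_ref = rowSums(pres_ref),
    max_depth = apply(reads$ref + reads$alt, 1, max),
    stringsAsFactors = FALSE)
  maf_cols <- as.data.frame(per_pool)
  names(maf_cols) <- paste0("maf_", colnames(reads$ref))
  cbind(out, maf_cols)
}
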