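FUNCTIONAL_CLASSES <- c("missense", "nonsense", "splice", "synonymous", "other")

#' Simulate an annotated variant universe
#'
#' Draws a set of bi-allelic SNVs with population alt-allele frequencies in a
#' low-frequency band, gene labels, functional classes and genomic positions.
#' This is the variant universe every downstream stage (pooling, filtering,
#' genotyping, association) operates on.
#'
#' @param n_variants number of variants.
#' @param maf_low,maf_high bounds of the alt-allele frequency law;
#'   `0 <= maf_low <= maf_high <= 0.5`.
#' @param seed optional integer seed (deterministic output when given).
#' @param freq_shape optional length-2 beta shape parameters; when supplied
#'   frequencies are drawn from the beta law rescaled to `[maf_low, maf_high]`
#'   instead of uniformly.
#' @param class_probs named probabilities over the functional classes
#'   `missense, nonsense, splice, synonymous, other`.
#' @param x_fraction expected fraction of variants placed on chromosome X so
#'   the X-exclusion rule of the merged association analysis is exercisable.
#' @param genes_per_variant expected number of variants per gene label.
#' @return a `data.frame` of class `population_model` with columns
#'   `id, chrom, pos, ref, alt, gene, func, af` (`af` = population alt-allele
#'   frequency).
#' @export
simulate_population <- function(n_variants, maf_low = 0.01, maf_high = 0.05,
                                seed = NULL, freq_shape = NULL,
                                class_probs = c(missense = 0.55, nonsense = 0.05,
                                                splice = 0.05, synonymous = 0.25,
                                                other = 0.10),
                                x_fraction = 0.04, genes_per_variant = 2) {
  stopifnot(n_variants >= 0, maf_low >= 0, maf_low <= maf_high, maf_high <= 0.5,
            x_fraction >= 0, x_fraction < 1)
  stopifnot(setequal(names(class_probs), FUNCTIONAL_CLASSES))
  maybe_seed(seed)
  n <- as.integer(n_variants)
  if (n == 0L) {
    pop <- data.frame(id = character(), chrom = character(), pos = integer(),
                      ref = character(), alt = character(), gene = character(),
                      func = character(), af = numeric(),
                      stringsAsFactors = FALSE)
    class(pop) <- c("population_model", "data.frame")
    return(pop)
  }
  af <- if (is.null(freq_shape)) {
    stats::runif(n, maf_low, maf_high)
  } else {
    maf_low + (maf_high - maf_low) * stats::rbeta(n, freq_shape[1], freq_shape[2])
  }
  chrom <- ifelse(stats::runif(n) < x_fraction, "X",
                  as.character(sample.int(22L, n, replace = TRUE)))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  n_genes <- max(1L, ceiling(n / genes_per_variant))
  pop <- data.frame(
    id = sprintf("var%04d", seq_len(n)),
    chrom = chrom,
    pos = sort(sample.int(5e7L, n, replace = FALSE)),
    ref = ref,
    alt = unname(alt),
    gene = sprintf("GENE%04d", sample.int(n_genes, n, replace = TRUE)),
    func = sample(FUNCTIONAL_CLASSES, n, replace = TRUE,
                  prob = class_probs[FUNCTIONAL_CLASSES]),
    af = af,
    stringsAsFactors = FALSE
  )
  class(pop) <- c("population_model", "data.frame")
  pop
}

#' Define a single-locus disease model
#'
#' Prevalence plus genotypic relative risks at one designated causal variant;
#' all other variants are null. With `causal = NULL` (or unit relative risks)
#' the model is fully null and disease status is independent of genotype.
#'
#' @param prevalence disease prevalence K in (0,1).
#' @param causal id of the causal variant, or `NULL` for the null model.
#' @param grr_het,grr_hom genotypic relative risks of the heterozygote and the
#'   risk-homozygote relative to the non-carrier (both `>= 0`, default 1).
#' @param label free-text model label.
#' @return a list of class `disease_model`.
#' @export
disease_model <- function(prevalence, causal = NULL, grr_het = 1, grr_hom = 1,
                          label = if (is.null(causal)) "null" else "single-locus") {
  stopifnot(prevalence > 0, prevalence < 1, grr_het >= 0, grr_hom >= 0,
            is.null(causal) || (is.character(causal) && length(causal) == 1L))
  structure(list(prevalence = prevalence, causal = causal,
                 grr_het = grr_het, grr_hom = grr_hom, label = label),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf("disease model '%s': K = %g", x$label, x$prevalence))
  if (!is.null(x$causal))
    cat(sprintf(", causal %s (GRR het %g, hom %g)", x$causal, x$grr_het, x$grr_hom))
  cat("\n")
  invisible(x)
}

#' Simulation configuration for the pooled-sequencing study design
#'
#' Collects the dimensioning and noise parameters of the emulated design:
#' 10 pools of 10 cases sequenced at a mean depth of 220x, a large mixed-sex
#' unselected reference cohort, genotyping noise, and the knobs that let the
#' equal-representation assumption of the pooled MAF estimator be violated
#' controllably.
#'
#' @param n_cases,n_controls,n_reference cohort sizes.
#' @param reference_male_fraction male fraction of the reference cohort.
#' @param pool_size,n_pools pooling design (default 10 x 10).
#' @param mean_depth mean per-pool read depth at a variant (default 220).
#' @param depth_dispersion negative-binomial overdispersion phi, so that
#'   depth variance = mu + phi * mu^2; 0 gives Poisson depths.
#' @param representation_concentration Dirichlet concentration governing how
#'   unequally samples contribute reads within a pool; `Inf` = exactly equal
#'   representation.
#' @param error_rate per-read symmetric allele flip probability.
#' @param missing_rate,genotyping_error_rate genotyping-stage noise.
#' @param seed master seed recorded with the configuration.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 100, n_controls = 100, n_reference = 6118,
                       reference_male_fraction = 0.43,
                       pool_size = 10, n_pools = 10,
                       mean_depth = 220, depth_dispersion = 0.05,
                       representation_concentration = Inf,
                       error_rate = 0.001,
                       missing_rate = 0.02, genotyping_error_rate = 0.001,
                       seed = NULL) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              n_reference = n_reference,
              reference_male_fraction = reference_male_fraction,
              pool_size = as.integer(pool_size), n_pools = as.integer(n_pools),
              mean_depth = mean_depth, depth_dispersion = depth_dispersion,
              representation_concentration = representation_concentration,
              error_rate = error_rate, missing_rate = missing_rate,
              genotyping_error_rate = genotyping_error_rate, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (pool_size * n_pools > n_cases)
      stop("pool_size * n_pools exceeds n_cases: ", pool_size * n_pools,
           " > ", n_cases)
    stopifnot(mean_depth > 0, depth_dispersion >= 0,
              representation_concentration > 0,
              error_rate >= 0, error_rate <= 1,
              missing_rate >= 0, missing_rate <= 1,
              genotyping_error_rate >= 0, genotyping_error_rate <= 1,
              reference_male_fraction >= 0, reference_male_fraction <= 1,
              n_reference >= 0, n_controls >= 0)
  })
  invisible(cfg)
}
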