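#' Sample a case-control cohort under a prevalence-constrained penetrance model
#'
#' Genotypes are drawn per variant from Hardy-Weinberg proportions at the
#' population allele frequencies. Disease status is assigned through the
#' penetrances at the designated causal variant (or independently at rate K
#' when the model is null). Cases are ascertained affected by rejection
#' sampling; controls are screened unaffected when `selected_controls = TRUE`
#' and sampled irrespective of status ("unselected") otherwise.
#'
#' Optional linkage-disequilibrium structure: if `attr(pop, "ld_pairs")` is a
#' data.frame with columns `tag`, `target`, `r2`, the target variant's
#' genotypes are drawn jointly with the tag's from a two-locus haplotype model
#' with `D = sqrt(r2 * pA qA pB qB)` (capped at Dmax).
#'
#' @param pop a `population_model` from [simulate_population()].
#' @param dis a [disease_model()].
#' @param n_cases,n_controls cohort sizes.
#' @param selected_controls screened-unaffected controls when `TRUE`.
#' @param seed optional integer seed.
#' @return list of class `genotype_dataset`: `samples` (data.frame with
#'   `sample_id`, `status` 1/0, `sex`), `genotypes` (samples x variants
#'   integer matrix of alt-allele copies), `variants` (the population table).
#' @export
solve_and_sample_cohort <- function(pop, dis, n_cases, n_controls,
                                    selected_controls = TRUE, seed = NULL) {
  stopifnot(inherits(pop, "population_model"), inherits(dis, "disease_model"),
            n_cases >= 0, n_controls >= 0)
  maybe_seed(seed)
  m <- nrow(pop)
  K <- dis$prevalence
  null_model <- is.null(dis$causal) || (dis$grr_het == 1 && dis$grr_hom == 1)
  causal_af <- NULL
  if (!null_model) {
    if (!dis$causal %in% pop$id)
      stop("causal variant ", dis$causal, " not in population")
    causal_af <- pop$af[match(dis$causal, pop$id)]
    f <- solve_penetrances(K, causal_af, dis$grr_het, dis$grr_hom,
                           variant = dis$causal)
  }

  draw_causal <- function(n_wanted, keep) {
    # rejection-sample (genotype, status) pairs at the causal locus until
    # n_wanted individuals satisfying keep(status) are collected
    g_out <- integer(0)
    while (length(g_out) < n_wanted) {
      batch <- max(1000L, ceiling((n_wanted - length(g_out)) / max(K, 1 - K)))
      g <- stats::rbinom(batch, 2L, causal_af)
      aff <- stats::rbinom(batch, 1L, f[g + 1L])
      g_out <- c(g_out, g[keep(aff)])
    }
    g_out[seq_len(n_wanted)]
  }

  n <- n_cases + n_controls
  status <- rep(c(1L, 0L), c(n_cases, n_controls))
  causal_geno <- NULL
  if (!null_model) {
    causal_geno <- integer(n)
    if (n_cases > 0)
      causal_geno[seq_len(n_cases)] <- draw_causal(n_cases, function(a) a == 1L)
    if (n_controls > 0) {
      idx <- n_cases + seq_len(n_controls)
      if (selected_controls) {
        causal_geno[idx] <- draw_causal(n_controls, function(a) a == 0L)
      } else {
        causal_geno[idx] <- stats::rbinom(n_controls, 2L, causal_af)
      }
    }
  } else if (!selected_controls && n_controls > 0) {
    # unselected controls carry the population's disease rate
    status[n_cases + seq_len(n_controls)] <- stats::rbinom(n_controls, 1L, K)
  }

  geno <- matrix(0L, nrow = n, ncol = m)
  ld <- attr(pop, "ld_pairs")
  ld_targets <- if (is.null(ld)) character(0) else ld$target
  for (j in seq_len(m)) {
    vid <- pop$id[j]
    if (!null_model && vid == dis$causal) {
      geno[, j] <- causal_geno
    } else if (!(vid %in% ld_targets)) {
      geno[, j] <- stats::rbinom(n, 2L, pop$af[j])
    }
  }
  if (!is.null(ld) && nrow(ld) > 0) {
    for (k in seq_len(nrow(ld))) {
      jt <- match(ld$tag[k], pop$id); jb <- match(ld$target[k], pop$id)
      if (is.na(jt) || is.na(jb)) stop("ld_pairs refers to unknown variant ids")
      geno[, jb] <- draw_linked(geno[, jt], pop$af[jt], pop$af[jb], ld$r2[k])
    }
  }

  ids <- c(sprintf("case%05d", seq_len(n_cases)),
           sprintf("ctrl%05d", seq_len(n_controls)))
  dimnames(geno) <- list(ids, pop$id)
  structure(list(
    samples = data.frame(sample_id = ids, status = status,
                         sex = rep("F", n), stringsAsFactors = FALSE),
    genotypes = geno,
    variants = as.data.frame(pop)
  ), class = "genotype_dataset")
}

# joint haplotype draw of a target locus given the tag's diploid genotypes;
# both loci in HWE marginally, pairwise LD set by the r2 target
draw_linked <- function(tag_geno, pA, pB, r2) {
  qA <- 1 - pA; qB <- 1 - pB
  D <- sqrt(r2 * pA * qA * pB * qB)
  D <- min(D, pA * qB, qA * pB)  # keep haplotype frequencies in [0,1]
  p_b_given_a1 <- (pA * pB + D) / pA
  p_b_given_a0 <- (qA * pB - D) / qA
  hap <- function(a_allele) stats::rbinom(length(a_allele), 1L,
                                          ifelse(a_allele == 1L,
                                                 p_b_given_a1, p_b_given_a0))
  # split diploid tag genotype into two haplotype alleles
  a1 <- as.integer(tag_geno >= 1L & (tag_geno == 2L |
                                     stats::runif(length(tag_geno)) < 0.5))
  a1[tag_geno == 2L] <- 1L
  a1[tag_geno == 0L] <- 0L
  a2 <- tag_geno - a1
  hap(a1) + hap(a2)
}

#' Assign pooled cases to sequencing pools
#'
#' Draws `pool_size * n_pools` distinct case samples and partitions them into
#' `n_pools` pools of exactly `pool_size` (the study design pooled a hundred
#' cases in pools of ten).
#'
#' @param dataset a `genotype_dataset`.
#' @param pool_size,n_pools pooling design.
#' @param seed optional integer seed.
#' @return data.frame with columns `sample_id`, `pool`.
#' @export
build_pools <- function(dataset, pool_size = 10, n_pools = 10, seed = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"), pool_size >= 1, n_pools >= 1)
  maybe_seed(seed)
  cases <- dataset$samples$sample_id[dataset$samples$status == 1L]
  need <- pool_size * n_pools
  if (length(cases) < need)
    stop("insufficient cases for pooling: need ", need, ", have ", length(cases))
  chosen <- sample(cases, need)
  data.frame(sample_id = chosen,
             pool = rep(sprintf("pool%02d", seq_len(n_pools)), each = pool_size),
             stringsAsFactors = FALSE)
}

#' Simulate pooled sequencing read counts
#'
#' For each pool and variant the total depth is negative-binomial around the
#' configured mean (Poisson when the dispersion is 0). Each read's source
#' sample is drawn from per-pool Dirichlet representation weights (exactly
#' equal representation when the concentration is infinite), and the read's
#' allele from the source sample's genotype with a symmetric per-read error.
#'
#' @param assignment pool assignment from [build_pools()].
#' @param dataset the `genotype_dataset` holding true genotypes.
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return list of class `pooled_reads` with integer matrices `ref` and `alt`
#'   (variants x pools; `ref + alt` = depth) and the `assignment`.
#' @export
simulate_pooled_reads <- function(assignment, dataset, cfg = sim_config(),
                                  seed = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            all(c("sample_id", "pool") %in% names(assignment)))
  if (!all(assignment$sample_id %in% dataset$samples$sample_id))
    stop("assignment refers to samples absent from the dataset")
  maybe_seed(seed)
  pools <- unique(assignment$pool)
  vids <- dataset$variants$id
  m <- length(vids)
  e <- cfg$error_rate
  phi <- cfg$depth_dispersion
  mu <- cfg$mean_depth
  alt <- ref <- matrix(0L, nrow = m, ncol = length(pools),
                       dimnames = list(vids, pools))
  for (jp in seq_along(pools)) {
    members <- assignment$sample_id[assignment$pool == pools[jp]]
    G <- dataset$genotypes[members, , drop = FALSE]
    if (anyNA(G)) stop("true genotypes must be complete for read simulation")
    w <- if (is.infinite(cfg$representation_concentration)) {
      rep(1 / length(members), length(members))
    } else {
      g <- stats::rgamma(length(members), shape = cfg$representation_concentration)
      g / sum(g)
    }
    depth <- if (phi == 0) stats::rpois(m, mu) else
      stats::rnbinom(m, mu = mu, size = 1 / phi)
    # per-read alt probability given source genotype g: g/2 + e (1 - g)
    p_alt <- G / 2 + e * (1 - G)
    for (v in seq_len(m)) {
      if (depth[v] == 0L) next
      n_src <- stats::rmultinom(1L, depth[v], w)[, 1L]
      a <- sum(stats::rbinom(length(members), n_src, p_alt[, v]))
      alt[v, jp] <- a
      ref[v, jp] <- depth[v] - a
    }
  }
  structure(list(ref = ref, alt = alt, assignment = assignment),
            class = "pooled_reads")
}

#' Simulate individual genotyping with missingness, errors and duplicate runs
#'
#' Entries are independently masked missing at `missing_rate` and flipped to a
#' uniformly chosen different genotype at `error_rate`. With `n_runs = 2` the
#' two matrices are independent noisy observations of the same truth, which is
#' what the duplicate-run concordance check consumes.
#'
#' @param dataset a `genotype_dataset`.
#' @param missing_rate,error_rate per-entry rates in [0,1].
#' @param n_runs number of replicate observation matrices.
#' @param seed optional integer seed.
#' @return list of `n_runs` observed genotype matrices (NA = missing).
#' @export
simulate_genotyping <- function(dataset, missing_rate = 0.02,
                                error_rate = 0.001, n_runs = 1, seed = NULL) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1, n_runs >= 1)
  maybe_seed(seed)
  G <- dataset$genotypes
  lapply(seq_len(n_runs), function(r) {
    obs <- G
    n <- length(obs)
    flip <- which(stats::runif(n) < error_rate)
    if (length(flip)) {
      # uniformly one of the two other genotype codes
      obs[flip] <- (obs[flip] + sample(1:2, length(flip), replace = TRUE)) %% 3L
    }
    obs[stats::runif(n) < missing_rate] <- NA_integer_
    obs
  })
}

#' Attach a simulated quantitative trait to a cohort
#'
#' `trait = intercept + beta_per_allele * genotype + N(0, noise_sd^2)` at the
#' designated causal variant (additive model).
#'
#' @param dataset a `genotype_dataset`.
#' @param causal variant id driving the trait.
#' @param beta_per_allele additive effect per alt-allele copy.
#' @param noise_sd residual standard deviation (> 0).
#' @param trait_name name of the new column in `dataset$samples`.
#' @param intercept trait mean for non-carriers.
#' @param seed optional integer seed.
#' @return the dataset with the trait column added.
#' @export
simulate_quantitative_traits <- function(dataset, causal, beta_per_allele,
                                         noise_sd, trait_name = "trait",
                                         intercept = 0, seed = NULL) {
  stopifnot(noise_sd > 0, causal %in% dataset$variants$id)
  maybe_seed(seed)
  g <- dataset$genotypes[, causal]
  dataset$samples[[trait_name]] <- intercept + beta_per_allele * g +
    stats::rnorm(length(g), 0, noise_sd)
  dataset
}

#' Simulate the three reference panels of the filtering design
#'
#' Produces (a) a large mixed-sex cohort panel with per-variant genotype
#' counts (a SISu-like population reference), (b) a frequency-only panel with
#' frequencies perturbed on the logit scale by `drift_sd` (a 1000 Genomes
#' EUR-like panel), and (c) a pooled technical-control panel built by pooling
#' and read-simulating an independent cohort (a scoliosis-like panel),
#' including per-pool presence calls for both alleles.
#'
#' @param pop a `population_model`.
#' @param drift_sd logit-scale drift SD of the frequency-only panel (>= 0).
#' @param n_reference cohort panel size.
#' @param male_fraction male fraction of the cohort panel (sex is recorded so
#'   X-chromosome exclusion can be exercised downstream).
#' @param cfg [sim_config()] used for the pooled technical-control panel.
#' @param seed optional integer seed.
#' @return list of class `reference_panels` with elements `cohort`
#'   (genotype-count panel), `freq` (frequency-only panel) and `pooled`
#'   (technical-control pooled panel).
#' @export
simulate_reference_panels <- function(pop, drift_sd = 0.05, n_reference = 6118,
                                      male_fraction = 0.43, cfg = sim_config(),
                                      seed = NULL) {
  stopifnot(inherits(pop, "population_model"), drift_sd >= 0,
            male_fraction >= 0, male_fraction <= 1)
  maybe_seed(seed)
  m <- nrow(pop)

  # (a) cohort panel with genotype counts and recorded sex
  n_male <- round(n_reference * male_fraction)
  counts <- data.frame(variant_id = pop$id, chrom = pop$chrom,
                       ref = pop$ref, alt = pop$alt,
                       n00 = integer(m), n01 = integer(m), n11 = integer(m),
                       stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    g <- stats::rbinom(n_reference, 2L, pop$af[j])
    counts$n00[j] <- sum(g == 0L)
    counts$n01[j] <- sum(g == 1L)
    counts$n11[j] <- sum(g == 2L)
  }
  counts$af <- (counts$n01 + 2 * counts$n11) / (2 * pmax(1L, n_reference))
  cohort <- structure(list(counts = counts, n = n_reference,
                           n_male = n_male, n_female = n_reference - n_male),
                      class = "cohort_panel")

  # (b) frequency-only panel with logit-scale drift
  af <- pop$af
  if (drift_sd > 0) {
    pos <- af > 0 & af < 1
    af[pos] <- stats::plogis(stats::qlogis(af[pos]) +
                             stats::rnorm(sum(pos), 0, drift_sd))
  }
  freq <- data.frame(variant_id = pop$id, af = af, stringsAsFactors = FALSE)

  # (c) pooled technical-control panel from an independent null cohort
  n_tc <- cfg$pool_size * cfg$n_pools
  tc <- solve_and_sample_cohort(pop, disease_model(0.5), n_cases = n_tc,
                                n_controls = 0, selected_controls = FALSE)
  tc_pools <- build_pools(tc, cfg$pool_size, cfg$n_pools)
  reads <- simulate_pooled_reads(tc_pools, tc, cfg)
  pres_alt <- call_pool_presence(reads$ref, reads$alt)
  pres_ref <- call_pool_presence(reads$alt, reads$ref)
  pooled <- structure(list(
    reads = reads,
    n_pools = cfg$n_pools,
    pools_present = rowSums(pres_alt),
    pools_present_ref = rowSums(pres_ref),
    af = stats::setNames(vapply(seq_len(m), function(v)
      estimate_overall_maf(reads$ref[v, ], reads$alt[v, ]), numeric(1)),
      rownames(reads$ref))
  ), class = "pooled_panel")

  structure(list(cohort = cohort, freq = freq, pooled = pooled),
            class = "reference_panels")
}
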