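# Shared fixture builders. Everything is generated in code; no stored data.

# a minimal variant summary table with every column the cascade consumes
blank_variant_table <- function(n) {
  data.frame(
    id = sprintf("v%03d", seq_len(n)),
    chrom = rep("1", n),
    pos = seq_len(n) * 1000L,
    ref = rep("A", n), alt = rep("G", n),
    gene = sprintf("G%03d", seq_len(n)),
    func = rep("missense", n),
    mapq = rep(60L, n),
    max_depth = rep(200L, n),
    suspected = rep(FALSE, n),
    pe_af = rep(0.05, n),
    pe_pools = rep(5L, n),
    pe_pools_ref = rep(10L, n),
    family_pool = rep(FALSE, n),
    cohort_af = rep(0.02, n),
    freq_af = rep(0.02, n),
    tc_af = rep(0.02, n),
    tc_pools = rep(3L, n),
    tc_pools_ref = rep(10L, n),
    alt_source_af = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
}

# random variant table spanning the cascade's edge cases (NA panels, low
# mapq, suspected flags, boundary pool counts and ratios)
random_variant_table <- function(n, seed) {
  set.seed(seed)
  vt <- blank_variant_table(n)
  vt$func <- sample(c("missense", "nonsense", "splice", "synonymous", "other"),
                    n, replace = TRUE)
  vt$mapq <- sample(c(60L, 40L, 19L, 10L), n, replace = TRUE,
                    prob = c(0.7, 0.15, 0.1, 0.05))
  vt$max_depth <- sample(c(5L, 9L, 10L, 50L, 300L), n, replace = TRUE,
                         prob = c(0.05, 0.05, 0.1, 0.3, 0.5))
  vt$suspected <- runif(n) < 0.1
  vt$gene <- sample(sprintf("G%03d", 1:40), n, replace = TRUE)
  vt$pe_af <- round(runif(n, 0, 0.25), 4)
  vt$pe_pools <- sample(0:10, n, replace = TRUE)
  vt$pe_pools_ref <- sample(0:10, n, replace = TRUE)
  vt$tc_pools <- sample(0:10, n, replace = TRUE)
  vt$tc_pools_ref <- sample(0:10, n, replace = TRUE)
  na_mask <- function(p) ifelse(runif(n) < p, NA_real_, round(runif(n, 0, 0.2), 4))
  vt$cohort_af <- na_mask(0.25)
  vt$freq_af <- na_mask(0.25)
  vt$tc_af <- na_mask(0.25)
  vt$alt_source_af <- ifelse(runif(n) < 0.5, NA_real_, round(runif(n, 0, 0.2), 4))
  vt$family_pool <- runif(n) < 0.3
  vt$chrom <- sample(c("1", "2", "7", "X"), n, replace = TRUE)
  vt$pos <- sample.int(2e6L, n)
  vt
}

# independent brute-force evaluation of the main cascade's keep decision,
# reimplementing every published rule directly from its verbal definition
brute_force_main_keep <- function(v, cfg) {
  # quality
  if (v$mapq < cfg$min_mapq) return(FALSE)
  if (v$max_depth < cfg$min_depth) return(FALSE)
  # functional class
  if (!v$func %in% cfg$functional_classes) return(FALSE)
  # presence in at least two case pools
  if (v$pe_pools < cfg$min_pe_pools) return(FALSE)
  # technical-control pools: "over five" excluded; "less than two" needs
  # frequency-panel MAF <= 0.05 (absent passes); 2..5 passes
  if (v$tc_pools > cfg$tc_high_cut) return(FALSE)
  if (v$tc_pools < cfg$tc_low_cut &&
      !is.na(v$freq_af) && v$freq_af > cfg$freq_maf_max) return(FALSE)
  # enrichment against every available panel
  for (af in c(v$cohort_af, v$freq_af, v$tc_af)) {
    if (is.na(af)) next
    if (af == 0 && v$pe_af > 0) next       # infinite enrichment
    if (af == 0 && v$pe_af == 0) return(FALSE)
    if (v$pe_af / af < cfg$enrichment_ratio_min) return(FALSE)
  }
  # blacklists and dbSNP suspected flag
  if (v$gene %in% cfg$blacklist_genes) return(FALSE)
  if (cfg$exclude_suspected && isTRUE(v$suspected)) return(FALSE)
  # alternative sources for variants no panel reports
  if (is.na(v$cohort_af) && is.na(v$freq_af) && is.na(v$tc_af) &&
      !is.na(v$alt_source_af)) {
    r <- if (v$alt_source_af == 0) {
      if (v$pe_af > 0) Inf else NA_real_
    } else v$pe_af / v$alt_source_af
    if (is.na(r) || r < cfg$enrichment_ratio_min) return(FALSE)
  }
  TRUE
}

# exact HWE heterozygote-count distribution by direct log-factorial
# enumeration (independent of the recurrence in the package)
oracle_hwe_pvalue <- function(n00, n01, n11) {
  n <- n00 + n01 + n11
  rare <- min(2 * n00 + n01, 2 * n11 + n01)
  if (rare == 0) return(1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- vapply(hets, function(h) {
    nr <- (rare - h) / 2
    nc <- n - h - nr
    lfactorial(n) - lfactorial(nr) - lfactorial(h) - lfactorial(nc) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n01, hets)]
  sum(p[p <= obs * (1 + 1e-10)])
}

# p-values for every heterozygote count of one (n, rare-allele-count) class,
# by the same log-factorial enumeration; used by the exhaustive sweep
oracle_hwe_class <- function(n, rare) {
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  nr <- (rare - hets) / 2
  nc <- n - hets - nr
  logp <- lfactorial(n) - lfactorial(nr) - lfactorial(hets) - lfactorial(nc) +
    hets * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
    lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  s <- sort(p)
  cum <- cumsum(s)
  idx <- findInterval(p * (1 + 1e-10), s)
  stats::setNames(cum[idx], hets)
}
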