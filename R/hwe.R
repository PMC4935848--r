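#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, the number of heterozygotes
#' under HWE follows the exact distribution
#' `P(n_ab | n, n_a) = n! / (n_aa! n_ab! n_bb!) * 2^n_ab * n_a! n_b! / (2n)!`.
#' The two-sided p-value sums the probabilities of all heterozygote counts
#' whose probability does not exceed that of the observed table (the
#' PLINK-style exact test; the chi-square approximation is invalid at the
#' low minor-allele counts this package targets). Probabilities are built by
#' the stable ratio recurrence from the distribution's mode.
#'
#' @param n00,n01,n11 genotype counts (major-hom, het, minor-hom); any
#'   orientation is accepted.
#' @return the exact two-sided p-value in (0, 1]. Monomorphic tables give 1.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' hwe_exact_test(99, 0, 1)
#' @export
hwe_exact_test <- function(n00, n01, n11) {
  stopifnot(length(n00) == 1L, length(n01) == 1L, length(n11) == 1L,
            n00 >= 0, n01 >= 0, n11 >= 0,
            n00 == round(n00), n01 == round(n01), n11 == round(n11))
  n <- n00 + n01 + n11
  if (n == 0) stop("empty genotype table: all counts are zero")
  rare <- min(2 * n00 + n01, 2 * n11 + n01)
  if (rare == 0) return(1)
  probs <- hwe_het_distribution(n, rare)
  obs <- probs[as.character(n01)]
  if (is.na(obs)) stop("heterozygote count ", n01,
                       " impossible given allele count ", rare)
  # relative tolerance guards ties against floating-point noise
  sum(probs[probs <= obs * (1 + 1e-10)])
}

# exact distribution of the heterozygote count given n individuals and
# `rare` copies of the rarer allele; returns probabilities named by het count.
# Built from the ratio recurrence P(h+2)/P(h) = 4 n_rr n_cc / ((h+2)(h+1)),
# accumulated in log space for stability, then normalised.
hwe_het_distribution <- function(n, rare) {
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  if (length(hets) == 1L) return(stats::setNames(1, hets))
  n_rr <- (rare - hets) / 2
  n_cc <- n - hets - n_rr
  k <- length(hets)
  lr <- log(4 * n_rr[-k] * n_cc[-k]) - log((hets[-k] + 2) * (hets[-k] + 1))
  logp <- c(0, cumsum(lr))
  p <- exp(logp - max(logp))
  stats::setNames(p / sum(p), hets)
}
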