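#' Allelic case-control chi-square test with odds ratio
#'
#' The 1-df Pearson chi-square without continuity correction on the 2x2
#' allele-count table (two alleles per person), matching the PLINK `--assoc`
#' basic allelic test. The odds ratio is the cross-product
#' `(a d) / (b c)` on allele counts, with a Woolf (log-OR normal
#' approximation) 95% confidence interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' Counts need not be integers (useful when reconstructing tables from
#' published frequencies). A zero margin leaves the statistic undefined
#' where division fails; a zero cell leaves the OR undefined unless
#' `correction = "haldane"` adds 0.5 to every cell for the OR/CI only.
#'
#' @param case_minor,case_major,control_minor,control_major allele counts.
#' @param conf_level confidence level of the Woolf interval.
#' @param correction `"none"` (default) or `"haldane"` (0.5 added to each
#'   cell for the OR and CI when any cell is zero).
#' @return list of class `allelic_test`: `chi2`, `p`, `or`, `ci_low`,
#'   `ci_high`, `case_maf`, `control_maf`, and logical flags
#'   `or_undefined`, `monomorphic`.
#' @export
allelic_chisq <- function(case_minor, case_major, control_minor, control_major,
                          conf_level = 0.95, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  a <- case_minor; b <- case_major; c <- control_minor; d <- control_major
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n_case <- a + b; n_ctrl <- c + d
  if (n_case <= 0 || n_ctrl <= 0) stop("both groups need positive allele counts")
  n <- n_case + n_ctrl
  minor <- a + c; major <- b + d
  monomorphic <- minor == 0 || major == 0
  if (monomorphic) {
    chi2 <- 0; p <- 1
  } else {
    e <- outer(c(n_case, n_ctrl), c(minor, major)) / n
    o <- matrix(c(a, c, b, d), 2)
    chi2 <- sum((o - e)^2 / e)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  zero_cell <- a == 0 || b == 0 || c == 0 || d == 0
  if (zero_cell && correction == "haldane") {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    zero_cell <- FALSE
  }
  if (zero_cell) {
    or <- ci_low <- ci_high <- NA_real_
  } else {
    or <- (a * d) / (b * c)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    ci_low <- exp(log(or) - z * se)
    ci_high <- exp(log(or) + z * se)
  }
  structure(list(chi2 = chi2, p = p, or = or, ci_low = ci_low,
                 ci_high = ci_high,
                 case_maf = case_minor / n_case,
                 control_maf = control_minor / n_ctrl,
                 or_undefined = is.na(or), monomorphic = monomorphic),
            class = "allelic_test")
}

#' Per-variant genotype counts by group
#'
#' @param genotypes samples x variants matrix coded 0/1/2 with NA missing.
#' @param status optional 1/0 case-control vector; when given, counts are
#'   returned per group.
#' @return data.frame with `variant_id`, `n00`, `n01`, `n11`, `n_missing`
#'   (and a `group` column when `status` is supplied).
#' @export
genotype_counts <- function(genotypes, status = NULL) {
  one <- function(G, label = NULL) {
    out <- data.frame(
      variant_id = colnames(G),
      n00 = colSums(G == 0L, na.rm = TRUE),
      n01 = colSums(G == 1L, na.rm = TRUE),
      n11 = colSums(G == 2L, na.rm = TRUE),
      n_missing = colSums(is.na(G)),
      stringsAsFactors = FALSE, row.names = NULL)
    if (!is.null(label)) out <- cbind(group = label, out)
    out
  }
  if (is.null(status)) return(one(genotypes))
  stopifnot(length(status) == nrow(genotypes))
  rbind(one(genotypes[status == 1L, , drop = FALSE], "case"),
        one(genotypes[status == 0L, , drop = FALSE], "control"))
}

#' Merge study controls with a population reference panel
#'
#' Sums genotype counts per shared variant. When the reference cohort is
#' mixed-sex (`mixed_sex_reference = TRUE`), X-chromosome variants are
#' flagged `x_excluded` and dropped from the merged table, since pooling
#' male and female X genotypes would distort allele counts; autosomal allele
#' frequencies are not assumed to differ between the sexes, so autosomal
#' variants merge unconditionally.
#'
#' @param controls,reference data.frames with `variant_id`, `chrom`, `n00`,
#'   `n01`, `n11` (and optionally allele columns `ref`/`alt`, checked for
#'   orientation agreement when present in both).
#' @param mixed_sex_reference does the reference contain both sexes?
#' @return list: `merged` (summed counts for retained variants) and
#'   `x_excluded` (character ids of dropped X variants).
#' @export
merge_reference <- function(controls, reference, mixed_sex_reference = TRUE) {
  shared <- intersect(controls$variant_id, reference$variant_id)
  ctl <- controls[match(shared, controls$variant_id), , drop = FALSE]
  ref <- reference[match(shared, reference$variant_id), , drop = FALSE]
  if (all(c("ref", "alt") %in% names(ctl)) &&
      all(c("ref", "alt") %in% names(ref))) {
    bad <- ctl$ref != ref$ref | ctl$alt != ref$alt
    if (any(bad))
      stop("allele orientation mismatch between cohorts for: ",
           paste(utils::head(shared[bad], 5), collapse = ", "),
           " (resolve upstream)")
  }
  merged <- data.frame(variant_id = shared, chrom = ctl$chrom,
                       n00 = ctl$n00 + ref$n00,
                       n01 = ctl$n01 + ref$n01,
                       n11 = ctl$n11 + ref$n11,
                       stringsAsFactors = FALSE)
  x_excluded <- character(0)
  if (mixed_sex_reference) {
    is_x <- merged$chrom %in% c("X", "chrX", "23")
    x_excluded <- merged$variant_id[is_x]
    merged <- merged[!is_x, , drop = FALSE]
  }
  list(merged = merged, x_excluded = x_excluded)
}

#' Differential genotype missingness test
#'
#' 2x2 test of missing vs observed genotype calls by case-control status:
#' Pearson chi-square (no continuity correction) when every expected cell is
#' at least 5, Fisher's exact test otherwise.
#'
#' @param case_missing,case_total,control_missing,control_total counts;
#'   totals are numbers of attempted genotypes per group.
#' @return the p-value.
#' @export
missingness_test <- function(case_missing, case_total,
                             control_missing, control_total) {
  stopifnot(case_total > 0, control_total > 0,
            case_missing <= case_total, control_missing <= control_total)
  tab <- matrix(c(case_missing, case_total - case_missing,
                  control_missing, control_total - control_missing),
                nrow = 2, byrow = TRUE)
  if (sum(tab[, 1]) == 0) return(1)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    stats::chisq.test(tab, correct = FALSE)$p.value
  } else {
    stats::fisher.test(tab)$p.value
  }
}

#' Sample-level genotyping QC
#'
#' Removes samples that failed genotyping for more than `max_missing`
#' variants among variants that were otherwise successfully genotyped
#' (variants missing for every sample are globally failed assays and count
#' against no sample).
#'
#' @param observed samples x variants observed genotype matrix (NA missing).
#' @param max_missing tolerated failures per sample (default 2, i.e. ">2"
#'   removed).
#' @param status optional 1/0 vector for per-group removal counts.
#' @return list: `kept`, `removed` (sample ids), `failed_variants`, and
#'   `removed_by_group` when `status` was given.
#' @export
sample_qc <- function(observed, max_missing = 2, status = NULL) {
  failed <- colnames(observed)[colSums(!is.na(observed)) == 0]
  usable <- setdiff(colnames(observed), failed)
  miss <- rowSums(is.na(observed[, usable, drop = FALSE]))
  drop <- miss > max_missing
  out <- list(kept = rownames(observed)[!drop],
              removed = rownames(observed)[drop],
              failed_variants = failed)
  if (!is.null(status)) {
    stopifnot(length(status) == nrow(observed))
    out$removed_by_group <- c(cases = sum(drop & status == 1L),
                              controls = sum(drop & status == 0L))
  }
  out
}

#' Duplicate-run genotype concordance
#'
#' Concordance over sample/variant pairs observed in both runs; samples with
#' at least one discordant genotype are listed for exclusion. Pairs missing
#' in either run are never counted as discordant.
#'
#' @param run1,run2 observed genotype matrices with dimnames.
#' @return list: `rate`, `n_pairs`, `n_discordant`, `excluded_samples`.
#' @export
concordance_check <- function(run1, run2) {
  samples <- intersect(rownames(run1), rownames(run2))
  variants <- intersect(colnames(run1), colnames(run2))
  if (length(samples) == 0 || length(variants) == 0)
    stop("no overlapping samples/variants between runs")
  a <- run1[samples, variants, drop = FALSE]
  b <- run2[samples, variants, drop = FALSE]
  joint <- !is.na(a) & !is.na(b)
  disc <- joint & a != b
  n_pairs <- sum(joint)
  if (n_pairs == 0) stop("no jointly observed genotype pairs")
  list(rate = 1 - sum(disc) / n_pairs,
       n_pairs = n_pairs,
       n_discordant = sum(disc),
       excluded_samples = samples[rowSums(disc) > 0])
}

#' Select variants for the second genotyping round
#'
#' Monomorphic variants are excluded first; among the rest, variants with an
#' odds ratio at or below `or_low` or at or above `or_high` are carried
#' forward (both boundaries inclusive). Variants failing HWE in controls are
#' flagged, not dropped.
#'
#' @param results data.frame with columns `or`, `monomorphic` and optionally
#'   `hwe_p_control`.
#' @param or_low,or_high selection boundaries (defaults 0.65 and 1.3).
#' @param hwe_alpha HWE flagging level (default 0.05).
#' @return the selected rows, with an `hwe_fail` logical column.
#' @export
select_round2 <- function(results, or_low = 0.65, or_high = 1.3,
                          hwe_alpha = 0.05) {
  stopifnot(or_low <= or_high)
  res <- results[!isTRUE_vec(results$monomorphic), , drop = FALSE]
  keep <- !is.na(res$or) & (res$or <= or_low | res$or >= or_high)
  res <- res[keep, , drop = FALSE]
  res$hwe_fail <- if ("hwe_p_control" %in% names(res))
    !is.na(res$hwe_p_control) & res$hwe_p_control < hwe_alpha
  else FALSE
  res
}

#' Additive-model quantitative-trait regression
#'
#' Ordinary least squares of the trait on the alt-allele count (0/1/2), the
#' standard additive single-variant model, with a two-sided Wald p-value.
#'
#' @param genotypes 0/1/2 vector (NA missing).
#' @param trait numeric trait vector, same length.
#' @return list: `beta`, `se`, `t`, `p`, `n`, `undefined` (TRUE when fewer
#'   than 3 complete pairs or the genotype has zero variance).
#' @export
quant_regression <- function(genotypes, trait) {
  stopifnot(length(genotypes) == length(trait))
  ok <- !is.na(genotypes) & !is.na(trait)
  g <- genotypes[ok]; y <- trait[ok]
  if (length(g) < 3 || stats::var(g) == 0)
    return(list(beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
                n = length(g), undefined = TRUE))
  fit <- stats::lm.fit(cbind(1, g), y)
  rss <- sum(fit$residuals^2)
  df <- length(g) - 2L
  sigma2 <- rss / df
  xtx_inv <- chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE])
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  beta <- unname(fit$coefficients[2])
  tval <- beta / se
  list(beta = beta, se = se, t = tval,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       n = length(g), undefined = FALSE)
}

#' Linkage disequilibrium between two variants from unphased genotypes
#'
#' Estimates the four haplotype frequencies by expectation-maximisation
#' (only the double heterozygote class is phase-ambiguous), then reports
#' `D' = D / Dmax` and `r^2 = D^2 / (pA qA pB qB)`.
#'
#' @param g1,g2 0/1/2 genotype vectors (NA pairs dropped).
#' @param max_iter,tol EM iteration cap and haplotype-frequency convergence
#'   tolerance.
#' @return list: `r2`, `dprime`, `D`, `hap` (frequencies of AB, Ab, aB, ab
#'   with A/B the alt alleles), `iterations`, `converged`.
#' @export
ld_stats <- function(g1, g2, max_iter = 1000, tol = 1e-10) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  stopifnot(n >= 2)
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2)
    stop("both variants need at least two distinct genotypes")
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  # haplotype frequencies h = c(AB, Ab, aB, ab); start at linkage equilibrium
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  n_dh <- sum(g1 == 1L & g2 == 1L)  # double heterozygotes: phase unknown
  # fixed (phase-known) haplotype counts from all other genotype classes
  cnt <- function(i, j) sum(g1 == i & g2 == j)
  base <- c(AB = 2 * cnt(2, 2) + cnt(2, 1) + cnt(1, 2),
            Ab = 2 * cnt(2, 0) + cnt(2, 1) + cnt(1, 0),
            aB = 2 * cnt(0, 2) + cnt(0, 1) + cnt(1, 2),
            ab = 2 * cnt(0, 0) + cnt(0, 1) + cnt(1, 0))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # E: split double heterozygotes between AB/ab and Ab/aB phases
    denom <- h[1] * h[4] + h[2] * h[3]
    w <- if (denom > 0) h[1] * h[4] / denom else 0.5
    counts <- base + n_dh * c(w, 1 - w, 1 - w, w)
    h_new <- counts / (2 * n)
    if (max(abs(h_new - h)) < tol) {
      h <- h_new; converged <- TRUE; break
    }
    h <- h_new
  }
  if (!converged)
    stop("EM did not converge after ", max_iter, " iterations")
  pA <- h[1] + h[2]; pB <- h[1] + h[3]
  D <- h[1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(r2 = unname(D^2 / (pA * (1 - pA) * pB * (1 - pB))),
       dprime = if (dmax > 0) unname(abs(D) / dmax) else NA_real_,
       D = unname(D),
       hap = stats::setNames(h, c("AB", "Ab", "aB", "ab")),
       iterations = it, converged = converged)
}

#' Case-control association table for a genotype matrix
#'
#' Per-variant allelic chi-square, OR with CI, group MAFs, HWE exact p-values
#' per group, differential missingness p, and QC flags - the column layout
#' of a standard association results table.
#'
#' @param genotypes samples x variants observed matrix (0/1/2, NA missing).
#' @param status 1/0 case-control vector.
#' @param hwe_alpha HWE flagging level in controls (default 0.05).
#' @param chrom optional chromosome labels per variant (for the
#'   `x_excluded` flag downstream; carried through).
#' @return data.frame, one row per variant.
#' @export
associate_cc <- function(genotypes, status, hwe_alpha = 0.05, chrom = NULL) {
  stopifnot(length(status) == nrow(genotypes))
  cases <- genotypes[status == 1L, , drop = FALSE]
  ctrls <- genotypes[status == 0L, , drop = FALSE]
  out <- lapply(seq_len(ncol(genotypes)), function(j) {
    gc <- cases[, j]; gm <- ctrls[, j]
    ca <- sum(gc, na.rm = TRUE); cn <- 2 * sum(!is.na(gc))
    ma <- sum(gm, na.rm = TRUE); mn <- 2 * sum(!is.na(gm))
    if (cn == 0 || mn == 0) return(NULL)
    at <- allelic_chisq(ca, cn - ca, ma, mn - ma)
    hwe_ctrl <- hwe_exact_test(sum(gm == 0, na.rm = TRUE),
                               sum(gm == 1, na.rm = TRUE),
                               sum(gm == 2, na.rm = TRUE))
    hwe_case <- hwe_exact_test(sum(gc == 0, na.rm = TRUE),
                               sum(gc == 1, na.rm = TRUE),
                               sum(gc == 2, na.rm = TRUE))
    miss_p <- missingness_test(sum(is.na(gc)), length(gc),
                               sum(is.na(gm)), length(gm))
    data.frame(variant_id = colnames(genotypes)[j],
               chrom = if (is.null(chrom)) NA_character_ else chrom[j],
               case_maf = at$case_maf, control_maf = at$control_maf,
               chi2 = at$chi2, p = at$p, or = at$or,
               ci_low = at$ci_low, ci_high = at$ci_high,
               hwe_p_case = hwe_case, hwe_p_control = hwe_ctrl,
               missingness_p = miss_p,
               monomorphic = at$monomorphic,
               hwe_fail = hwe_ctrl < hwe_alpha,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Allelic association from merged genotype-count tables
#'
#' Runs [allelic_chisq()] on case counts vs merged control counts (as from
#' [merge_reference()]), plus HWE exact tests in each group.
#'
#' @param case_counts,control_counts data.frames with `variant_id`, `n00`,
#'   `n01`, `n11`.
#' @param hwe_alpha HWE flagging level (applied to the control table).
#' @return data.frame, one row per shared variant.
#' @export
associate_counts <- function(case_counts, control_counts, hwe_alpha = 0.05) {
  shared <- intersect(case_counts$variant_id, control_counts$variant_id)
  ca <- case_counts[match(shared, case_counts$variant_id), ]
  co <- control_counts[match(shared, control_counts$variant_id), ]
  out <- lapply(seq_along(shared), function(i) {
    a <- ca$n01[i] + 2 * ca$n11[i]
    n_case <- 2 * (ca$n00[i] + ca$n01[i] + ca$n11[i])
    c_ <- co$n01[i] + 2 * co$n11[i]
    n_ctrl <- 2 * (co$n00[i] + co$n01[i] + co$n11[i])
    if (n_case == 0 || n_ctrl == 0) return(NULL)
    at <- allelic_chisq(a, n_case - a, c_, n_ctrl - c_)
    data.frame(variant_id = shared[i],
               case_maf = at$case_maf, control_maf = at$control_maf,
               chi2 = at$chi2, p = at$p, or = at$or,
               ci_low = at$ci_low, ci_high = at$ci_high,
               hwe_p_case = hwe_exact_test(ca$n00[i], ca$n01[i], ca$n11[i]),
               hwe_p_control = hwe_exact_test(co$n00[i], co$n01[i], co$n11[i]),
               monomorphic = at$monomorphic,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (!is.null(res)) {
    res$hwe_fail <- res$hwe_p_control < hwe_alpha
    rownames(res) <- NULL
  }
  res
}
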