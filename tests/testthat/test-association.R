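test_that("allelic chi-square equals the textbook Pearson statistic", {
  # hand-computed: chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  at <- allelic_chisq(10, 90, 5, 95)
  chi2_hand <- 200 * (10 * 95 - 90 * 5)^2 / (100 * 100 * 15 * 185)
  expect_equal(at$chi2, chi2_hand, tolerance = 1e-12)
  expect_equal(at$p, pchisq(chi2_hand, 1, lower.tail = FALSE))

  # independent route: R's own Pearson test without correction
  set.seed(9)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 40) + 1, 2)
    at <- allelic_chisq(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(at$chi2, unname(ct$statistic), tolerance = 1e-10)
    expect_equal(at$p, ct$p.value, tolerance = 1e-10)
  }
})

test_that("identical groups give the exact null result", {
  at <- allelic_chisq(12, 88, 12, 88)
  expect_equal(at$chi2, 0)
  expect_equal(at$p, 1)
  expect_equal(at$or, 1)
  expect_true(at$ci_low <= 1 && at$ci_high >= 1)
})

test_that("odds ratio from published MAFs reproduces the cross-product", {
  # case MAF 0.046 on 2706 alleles vs merged-control MAF 0.035 on 13634
  at <- allelic_chisq(0.046 * 2706, (1 - 0.046) * 2706,
                      0.035 * 13634, (1 - 0.035) * 13634)
  expect_equal(round(at$or, 2), 1.33)
  expect_true(at$ci_low < at$or && at$or < at$ci_high)
})

test_that("OR inverts under swapping allele labels in both groups", {
  set.seed(10)
  for (i in 1:25) {
    a <- rpois(1, 20) + 1; b <- rpois(1, 200) + 1
    c_ <- rpois(1, 15) + 1; d <- rpois(1, 250) + 1
    x <- allelic_chisq(a, b, c_, d)
    y <- allelic_chisq(b, a, d, c_)
    expect_equal(x$or, 1 / y$or, tolerance = 1e-12)
    expect_equal(x$p, y$p, tolerance = 1e-12)
  }
})

test_that("zero cells flag the OR unless the Haldane correction is asked", {
  at <- allelic_chisq(0, 100, 5, 95)
  expect_true(at$or_undefined)
  expect_true(is.na(at$or))
  ha <- allelic_chisq(0, 100, 5, 95, correction = "haldane")
  expect_false(ha$or_undefined)
  expect_equal(ha$or, (0.5 * 95.5) / (100.5 * 5.5), tolerance = 1e-12)
})

test_that("merging a reference panel adds counts and excludes X variants", {
  ctl <- data.frame(variant_id = c("v1", "v2"), chrom = c("1", "X"),
                    n00 = c(900L, 800L), n01 = c(95L, 90L), n11 = c(5L, 10L))
  ref <- data.frame(variant_id = c("v1", "v2"), chrom = c("1", "X"),
                    n00 = c(5900L, 5000L), n01 = c(210L, 200L),
                    n11 = c(8L, 20L))
  mg <- merge_reference(ctl, ref, mixed_sex_reference = TRUE)
  expect_equal(mg$merged$variant_id, "v1")
  expect_equal(unlist(mg$merged[1, c("n00", "n01", "n11")], use.names = FALSE),
               c(6800L, 305L, 13L))
  expect_equal(mg$x_excluded, "v2")

  # single-sex reference keeps X variants
  all_in <- merge_reference(ctl, ref, mixed_sex_reference = FALSE)
  expect_equal(nrow(all_in$merged), 2)
  # count conservation
  expect_equal(rowSums(all_in$merged[, c("n00", "n01", "n11")]),
               rowSums(ctl[, c("n00", "n01", "n11")]) +
                 rowSums(ref[, c("n00", "n01", "n11")]))

  # allele-orientation mismatches are an upstream error
  ctl$ref <- c("A", "C"); ctl$alt <- c("G", "T")
  ref$ref <- c("G", "C"); ref$alt <- c("A", "T")
  expect_error(merge_reference(ctl, ref), "orientation mismatch")
})

test_that("differential missingness test switches chi-square and Fisher", {
  expect_gt(missingness_test(10, 100, 10, 100), 0.99)
  expect_equal(missingness_test(0, 100, 0, 100), 1)

  # gross differential missingness: Fisher route, compare to the
  # hypergeometric tail computed directly
  p <- missingness_test(50, 100, 1, 100)
  expect_lt(p, 1e-6)
  expect_equal(p, stats::fisher.test(matrix(c(50, 50, 1, 99), 2,
                                            byrow = TRUE))$p.value,
               tolerance = 1e-12)
  # the one-sided hypergeometric tail bounds the two-sided p from below
  tail_hyper <- sum(stats::dhyper(50:51, 51, 149, 100))
  expect_gte(p, tail_hyper)
})

test_that("sample QC drops samples failing >2 otherwise-successful assays", {
  g <- matrix(0L, 5, 30, dimnames = list(paste0("s", 1:5), paste0("v", 1:30)))
  g[, "v30"] <- NA_integer_          # globally failed assay
  g["s1", c("v1", "v2", "v3")] <- NA_integer_  # 3 failures: removed
  g["s2", c("v1", "v2")] <- NA_integer_        # 2 failures: kept
  qc <- sample_qc(g, max_missing = 2, status = c(1L, 1L, 0L, 0L, 0L))
  expect_equal(qc$removed, "s1")
  expect_setequal(qc$kept, c("s2", "s3", "s4", "s5"))
  expect_equal(qc$failed_variants, "v30")
  expect_equal(unname(qc$removed_by_group), c(1L, 0L))

  # the failed assay never counts against a sample
  g2 <- g
  g2["s2", "v30"] <- NA_integer_
  expect_false("s2" %in% sample_qc(g2, 2)$removed)
})

test_that("concordance counts jointly observed pairs only", {
  m <- matrix(0L, 350, 28, dimnames = list(sprintf("s%03d", 1:350),
                                           paste0("v", 1:28)))
  a <- m; b <- m
  expect_equal(concordance_check(a, b)$rate, 1)
  expect_equal(length(concordance_check(a, b)$excluded_samples), 0)

  # one discordant genotype among 350 x 28 pairs
  b["s001", "v1"] <- 1L
  cc <- concordance_check(a, b)
  expect_equal(cc$rate, 1 - 1 / 9800)
  expect_equal(cc$excluded_samples, "s001")

  # missing entries are never discordant
  b["s002", "v2"] <- NA_integer_
  a["s002", "v2"] <- 2L
  cc2 <- concordance_check(a, b)
  expect_equal(cc2$n_pairs, 9800 - 1)
  expect_equal(cc2$excluded_samples, "s001")

  expect_error(concordance_check(a, m[0, 0]), "no overlapping")
})

test_that("round-2 selection uses inclusive OR boundaries", {
  res <- data.frame(variant_id = paste0("v", 1:6),
                    or = c(1.30, 0.66, 0.65, 1.29, 2.0, 1.0),
                    monomorphic = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
                    hwe_p_control = c(0.5, 0.5, 0.01, 0.5, 0.5, 0.5))
  sel <- select_round2(res)
  # v1 (1.30 inclusive), v3 (0.65 inclusive); v2/v4 inside the window;
  # v5 monomorphic despite extreme OR
  expect_setequal(sel$variant_id, c("v1", "v3"))
  expect_equal(sel$hwe_fail[sel$variant_id == "v3"], TRUE)
})

test_that("quantitative regression recovers exact and degenerate cases", {
  g <- c(0, 1, 2, 0, 1, 2, 1, 0)
  fit <- quant_regression(g, 2 * g)
  expect_equal(fit$beta, 2, tolerance = 1e-12)
  expect_lt(fit$p, 1e-10)

  expect_true(quant_regression(rep(1, 10), rnorm(10))$undefined)
  expect_true(quant_regression(c(0, 1), c(1, 2))$undefined)

  # agreement with lm() on noisy data
  set.seed(11)
  g <- rbinom(200, 2, 0.3); y <- 0.4 * g + rnorm(200)
  fit <- quant_regression(g, y)
  ref <- summary(stats::lm(y ~ g))$coefficients["g", ]
  expect_equal(fit$beta, unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(fit$se, unname(ref["Std. Error"]), tolerance = 1e-10)
  expect_equal(fit$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("regression p-values are uniform under permutation", {
  set.seed(12)
  g <- rbinom(100, 2, 0.3); y <- rnorm(100)
  ps <- vapply(1:500, function(i) quant_regression(g, sample(y))$p, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("LD statistics recover constructed haplotype structure", {
  # identical columns tag perfectly
  set.seed(13)
  g <- rbinom(500, 2, 0.3)
  ld <- ld_stats(g, g)
  expect_equal(ld$r2, 1, tolerance = 1e-6)
  expect_equal(ld$dprime, 1, tolerance = 1e-6)

  # independent variants: r2 near zero
  g1 <- rbinom(10000, 2, 0.3); g2 <- rbinom(10000, 2, 0.4)
  expect_lt(ld_stats(g1, g2)$r2, 0.01)

  # D = Dmax with unequal frequencies: D' = 1 but r2 < 1.
  # haplotype frequencies AB/Ab/aB/ab = 0.3/0/0.3/0.4 (pA=0.3, pB=0.6,
  # D = 0.12 = Dmax, r2 = D^2/(pA qA pB qB) = 2/7)
  haps <- rep(c("AB", "aB", "ab"), times = c(300, 300, 400))
  set.seed(14)
  haps <- sample(haps)
  h1 <- haps[1:500]; h2 <- haps[501:1000]
  g1 <- (substr(h1, 1, 1) == "A") + (substr(h2, 1, 1) == "A")
  g2 <- (substr(h1, 2, 2) == "B") + (substr(h2, 2, 2) == "B")
  ld <- ld_stats(g1, g2)
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  hab <- (sum(h1 == "AB") + sum(h2 == "AB")) / 1000
  D_expected <- hab - pA * pB
  dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  expect_equal(ld$dprime, D_expected / dmax, tolerance = 1e-6)
  expect_equal(ld$r2,
               D_expected^2 / (pA * (1 - pA) * pB * (1 - pB)),
               tolerance = 1e-6)
  expect_lt(ld$r2, 1)

  expect_error(ld_stats(rep(1, 10), rbinom(10, 2, 0.5)), "distinct genotypes")
})

test_that("associate_cc produces a coherent per-variant table", {
  pop <- simulate_population(20, 0.05, 0.2, seed = 15)
  coh <- solve_and_sample_cohort(pop, disease_model(0.05), 300, 300, seed = 15)
  obs <- simulate_genotyping(coh, 0.02, 0, seed = 16)[[1]]
  res <- associate_cc(obs, coh$samples$status)
  expect_equal(nrow(res), 20)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$ci_low <= res$or & res$or <= res$ci_high, na.rm = TRUE))
  expect_true(all(res$or > 0, na.rm = TRUE))

  # spot-check one variant against a direct allelic test
  j <- 5
  st <- coh$samples$status
  gc <- obs[st == 1, j]; gm <- obs[st == 0, j]
  at <- allelic_chisq(sum(gc, na.rm = TRUE),
                      2 * sum(!is.na(gc)) - sum(gc, na.rm = TRUE),
                      sum(gm, na.rm = TRUE),
                      2 * sum(!is.na(gm)) - sum(gm, na.rm = TRUE))
  expect_equal(res$p[j], at$p)
  expect_equal(res$or[j], at$or)
})
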