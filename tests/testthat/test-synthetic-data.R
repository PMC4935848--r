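test_that("simulate_population respects bounds, the empty case, and its law", {
  expect_equal(nrow(simulate_population(0)), 0L)

  pop <- simulate_population(1000, 0.01, 0.05, seed = 1)
  expect_true(all(pop$af >= 0.01 & pop$af <= 0.05))
  expect_false(any(duplicated(pop$id)))
  expect_true(all(pop$pos >= 1))
  expect_true(all(pop$func %in% c("missense", "nonsense", "splice",
                                  "synonymous", "other")))

  # uniform law: mean (a+b)/2 within 3 standard errors, SE = (b-a)/sqrt(12 n)
  big <- simulate_population(10000, 0.01, 0.05, seed = 1)
  se <- (0.05 - 0.01) / sqrt(12 * 10000)
  expect_lt(abs(mean(big$af) - 0.03), 3 * se)

  expect_error(simulate_population(10, 0.05, 0.01), "maf_low")
})

test_that("generators are bit-identical under the same seed", {
  pop1 <- simulate_population(50, seed = 42)
  pop2 <- simulate_population(50, seed = 42)
  expect_identical(pop1, pop2)

  dis <- disease_model(0.05, pop1$id[1], 2, 4)
  c1 <- solve_and_sample_cohort(pop1, dis, 120, 60, seed = 7)
  c2 <- solve_and_sample_cohort(pop1, dis, 120, 60, seed = 7)
  expect_identical(c1, c2)

  p1 <- build_pools(c1, 10, 10, seed = 3)
  expect_identical(p1, build_pools(c1, 10, 10, seed = 3))
  cfg <- sim_config(n_cases = 120)
  expect_identical(simulate_pooled_reads(p1, c1, cfg, seed = 9),
                   simulate_pooled_reads(p1, c1, cfg, seed = 9))
  expect_identical(simulate_genotyping(c1, 0.1, 0.01, 2, seed = 5),
                   simulate_genotyping(c1, 0.1, 0.01, 2, seed = 5))
})

test_that("penetrance solver recovers the prevalence identity exactly", {
  set.seed(11)
  for (i in 1:50) {
    K <- runif(1, 0.01, 0.3); p <- runif(1, 0.005, 0.4)
    rh <- runif(1, 0.5, 3); rm <- runif(1, 0.5, 5)
    f <- tryCatch(solve_penetrances(K, p, rh, rm), error = function(e) NULL)
    if (is.null(f)) next
    q <- 1 - p
    expect_lt(abs(q^2 * f[1] + 2 * p * q * f[2] + p^2 * f[3] - K), 1e-12)
  }
  expect_error(solve_penetrances(0.5, 0.05, 1, 30, variant = "rs1"),
               "infeasible.*rs1")
})

test_that("cohort sampling matches the penetrance algebra", {
  pop <- simulate_population(3, 0.02, 0.04, seed = 2)
  pop$af[1] <- 0.05

  # null model: case and control frequencies both near the population value
  null_coh <- solve_and_sample_cohort(pop, disease_model(0.05), 2000, 2000,
                                      selected_controls = FALSE, seed = 3)
  st <- null_coh$samples$status
  af_case <- mean(null_coh$genotypes[st == 1, 1]) / 2
  af_ctrl <- mean(null_coh$genotypes[st == 0, 1][1:sum(st == 0)]) / 2
  se <- sqrt(0.05 * 0.95 / (2 * 2000))
  expect_lt(abs(af_case - 0.05), 4 * se)
  expect_lt(abs(af_case - af_ctrl), 6 * se)

  # K=0.05, p=0.05, Rhet=1.65, Rhom=3: case AF from direct penetrance
  # algebra f0 = K/(q^2 + 2pq Rhet + p^2 Rhom) gives 0.080502
  dis <- disease_model(0.05, pop$id[1], 1.65, 3)
  coh <- solve_and_sample_cohort(pop, dis, 4000, 0, seed = 4)
  af_case <- mean(coh$genotypes[, 1]) / 2
  expect_lt(abs(af_case - 0.08050152), 3 * sqrt(0.0805 * 0.9195 / 8000))

  # screened controls deplete the risk allele relative to unselected ones
  dis3 <- disease_model(0.05, pop$id[1], 3, 9)
  f <- solve_penetrances(0.05, 0.05, 3, 9)
  sel_exp <- group_frequencies(f, 0.05, controls_selected = TRUE)$control_af
  expect_lt(sel_exp, 0.05)
  sel <- solve_and_sample_cohort(pop, dis3, 10, 4000,
                                 selected_controls = TRUE, seed = 5)
  uns <- solve_and_sample_cohort(pop, dis3, 10, 4000,
                                 selected_controls = FALSE, seed = 6)
  af_sel <- mean(sel$genotypes[sel$samples$status == 0, 1]) / 2
  af_uns <- mean(uns$genotypes[11:4010, 1]) / 2
  expect_lt(abs(af_sel - sel_exp), 3 * sqrt(sel_exp * (1 - sel_exp) / 8000))
  expect_lt(abs(af_uns - 0.05), 3 * sqrt(0.05 * 0.95 / 8000))

  # infeasible penetrance names the variant
  expect_error(
    solve_and_sample_cohort(pop, disease_model(0.5, pop$id[2], 1, 30), 10, 0),
    pop$id[2])
})

test_that("pool assignment partitions cases exactly", {
  pop <- simulate_population(5, seed = 1)
  coh <- solve_and_sample_cohort(pop, disease_model(0.05), 100, 20, seed = 1)
  asg <- build_pools(coh, 10, 10, seed = 2)
  expect_equal(nrow(asg), 100)
  expect_false(any(duplicated(asg$sample_id)))
  expect_equal(as.vector(table(asg$pool)), rep(10L, 10))
  cases <- coh$samples$sample_id[coh$samples$status == 1]
  expect_setequal(asg$sample_id, cases)

  # singleton pools
  one <- build_pools(coh, 1, 5, seed = 3)
  expect_equal(as.vector(table(one$pool)), rep(1L, 5))

  expect_error(build_pools(coh, 10, 11, seed = 4), "insufficient")
})

test_that("pooled reads follow the binomial law of the pool allele fraction", {
  # pool of 10 with 2 heterozygote carriers: true allele fraction
  # 2 / (2 * 10) = 0.10; with no error the alt-read fraction is binomial
  pop <- simulate_population(30, 0.01, 0.05, seed = 8)
  coh <- solve_and_sample_cohort(pop, disease_model(0.05), 10, 0, seed = 8)
  coh$genotypes[] <- 0L
  coh$genotypes[1:2, ] <- 1L
  asg <- data.frame(sample_id = coh$samples$sample_id, pool = "pool01")
  cfg <- sim_config(n_cases = 10, n_pools = 1, mean_depth = 220,
                    depth_dispersion = 0, error_rate = 0)
  reads <- simulate_pooled_reads(asg, coh, cfg, seed = 9)
  depth <- sum(reads$ref + reads$alt)
  frac <- sum(reads$alt) / depth
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / depth))

  # monomorphic pool with zero error: never an alt read
  coh$genotypes[] <- 0L
  mono <- simulate_pooled_reads(asg, coh, cfg, seed = 10)
  expect_true(all(mono$alt == 0))
  expect_true(all(mono$ref + mono$alt >= 0))
})

test_that("read counts conserve depth and respect the depth law", {
  pop <- simulate_population(40, seed = 3)
  coh <- solve_and_sample_cohort(pop, disease_model(0.05), 100, 0, seed = 3)
  asg <- build_pools(coh, 10, 10, seed = 3)
  cfg <- sim_config(mean_depth = 220, depth_dispersion = 0.05)
  reads <- simulate_pooled_reads(asg, coh, cfg, seed = 4)
  expect_true(all(reads$ref >= 0 & reads$alt >= 0))
  depth <- reads$ref + reads$alt
  expect_lt(abs(mean(depth) - 220), 220 * 0.05)  # mean near configured value
})

test_that("unequal representation inflates the alt-fraction variance", {
  # Dirichlet concentration -> infinity reproduces equal-representation
  # binomial variance; small concentration strictly inflates it
  pop <- simulate_population(1, 0.05, 0.05, seed = 5)
  coh <- solve_and_sample_cohort(pop, disease_model(0.05), 10, 0, seed = 5)
  coh$genotypes[] <- 0L
  coh$genotypes[1:2, 1] <- 1L  # true pool fraction 0.10
  asg <- data.frame(sample_id = coh$samples$sample_id, pool = "pool01")
  run <- function(conc, n_rep) {
    cfg <- sim_config(n_cases = 10, n_pools = 1, mean_depth = 100,
                      depth_dispersion = 0, error_rate = 0,
                      representation_concentration = conc)
    set.seed(77)
    vapply(seq_len(n_rep), function(i) {
      r <- simulate_pooled_reads(asg, coh, cfg)
      sum(r$alt) / sum(r$alt + r$ref)
    }, numeric(1))
  }
  n_rep <- 10000
  v_equal <- var(run(Inf, n_rep))
  v_skew <- var(run(0.3, n_rep))
  v_binom <- 0.1 * 0.9 / 100
  expect_lt(abs(v_equal - v_binom), 0.15 * v_binom)
  expect_gt(v_skew, 1.5 * v_equal)
})

test_that("genotyping noise matches the closed-form discordance rate", {
  pop <- simulate_population(50, seed = 6)
  coh <- solve_and_sample_cohort(pop, disease_model(0.05), 1000, 1000, seed = 6)

  # noiseless duplicate runs are perfectly concordant
  clean <- simulate_genotyping(coh, 0, 0, n_runs = 2, seed = 7)
  expect_identical(clean[[1]], clean[[2]])
  expect_equal(concordance_check(clean[[1]], clean[[2]])$rate, 1)

  # two runs at error rate e disagree with probability 2e(1-e) + e^2/2:
  # exactly one run flips, or both flip to different values (each flip
  # picks uniformly between the 2 other codes)
  e <- 0.02
  runs <- simulate_genotyping(coh, 0, e, n_runs = 2, seed = 8)
  cc <- concordance_check(runs[[1]], runs[[2]])
  p_disc <- 2 * e * (1 - e) + e^2 / 2
  se <- sqrt(p_disc * (1 - p_disc) / cc$n_pairs)
  expect_lt(abs((1 - cc$rate) - p_disc), 3 * se)

  # saturation
  all_na <- simulate_genotyping(coh, 1, 0, seed = 9)[[1]]
  expect_true(all(is.na(all_na)))
})

test_that("reference panels expose drift, sex and the pooled design", {
  pop <- simulate_population(30, seed = 10)
  cfg <- sim_config(n_cases = 100)

  still <- simulate_reference_panels(pop, drift_sd = 0, n_reference = 400,
                                     cfg = cfg, seed = 11)
  expect_equal(still$freq$af, pop$af)

  pan <- simulate_reference_panels(pop, drift_sd = 0.05, n_reference = 6118,
                                   male_fraction = 0.43, cfg = cfg, seed = 12)
  expect_equal(pan$cohort$n, 6118)
  expect_equal(pan$cohort$n_male, round(6118 * 0.43))
  expect_equal(pan$cohort$n_male + pan$cohort$n_female, 6118)
  with(pan$cohort$counts, expect_true(all(n00 + n01 + n11 == 6118)))

  # technical-control panel keeps the 10x10 pooled design
  expect_equal(pan$pooled$n_pools, 10)
  expect_equal(ncol(pan$pooled$reads$ref), 10)
  expect_true(all(pan$pooled$pools_present <= 10))
})

test_that("simulated quantitative traits recover the additive slope", {
  pop <- simulate_population(2, 0.2, 0.3, seed = 13)
  coh <- solve_and_sample_cohort(pop, disease_model(0.05), 2000, 0, seed = 13)

  # null slope
  coh0 <- simulate_quantitative_traits(coh, pop$id[1], 0, 1, seed = 14)
  fit0 <- quant_regression(coh0$genotypes[, 1], coh0$samples$trait)
  expect_lt(abs(fit0$beta), 3 * fit0$se)

  # beta = 0.5 recovered within 3 OLS standard errors
  coh1 <- simulate_quantitative_traits(coh, pop$id[1], 0.5, 1, seed = 15)
  fit1 <- quant_regression(coh1$genotypes[, 1], coh1$samples$trait)
  expect_lt(abs(fit1$beta - 0.5), 3 * fit1$se)

  # noiseless limit
  coh2 <- simulate_quantitative_traits(coh, pop$id[1], 1, 1e-9, seed = 16)
  fit2 <- quant_regression(coh2$genotypes[, 1], coh2$samples$trait)
  expect_equal(fit2$beta, 1, tolerance = 1e-6)
})

test_that("LD-paired variants reach the target r-squared", {
  pop <- simulate_population(2, 0.2, 0.3, seed = 17)
  pop$af[2] <- pop$af[1]  # equal frequencies so r2 = 0.9 is attainable
  attr(pop, "ld_pairs") <- data.frame(tag = pop$id[1], target = pop$id[2],
                                      r2 = 0.9)
  coh <- solve_and_sample_cohort(pop, disease_model(0.05), 5000, 0, seed = 18)
  ld <- ld_stats(coh$genotypes[, 1], coh$genotypes[, 2])
  expect_equal(ld$r2, 0.9, tolerance = 0.08)
})
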