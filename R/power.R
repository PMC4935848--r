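#' Solve genotype penetrances from prevalence and genotypic relative risks
#'
#' Under a single bi-allelic locus in Hardy-Weinberg proportions with risk
#' allele frequency `p`, prevalence `K` constrains the penetrances through
#' `K = q^2 f0 + 2 p q f1 + p^2 f2` with `f1 = Rhet f0`, `f2 = Rhom f0`,
#' giving `f0 = K / (q^2 + 2 p q Rhet + p^2 Rhom)`. This is the penetrance
#' construction of the classic case-control discrete-trait power model.
#'
#' @param prevalence disease prevalence K in (0,1).
#' @param raf risk (alt) allele frequency p in (0,1).
#' @param grr_het,grr_hom genotypic relative risks (>= 0).
#' @param variant optional variant id used in the infeasibility error message.
#' @return named numeric vector `c(f0, f1, f2)`, all in [0,1].
#' @export
solve_penetrances <- function(prevalence, raf, grr_het, grr_hom, variant = NULL) {
  stopifnot(prevalence > 0, prevalence < 1, raf > 0, raf < 1,
            grr_het >= 0, grr_hom >= 0)
  q <- 1 - raf
  f0 <- prevalence / (q^2 + 2 * raf * q * grr_het + raf^2 * grr_hom)
  f <- c(f0 = f0, f1 = grr_het * f0, f2 = grr_hom * f0)
  if (any(f > 1 + 1e-12))
    stop("penetrance model infeasible",
         if (!is.null(variant)) paste0(" for variant ", variant),
         ": max penetrance ", format(max(f)), " > 1")
  pmin(f, 1)
}

#' Case and control genotype/allele frequencies under a penetrance model
#'
#' Cases carry genotype g with probability proportional to the population
#' Hardy-Weinberg frequency times the penetrance (normalised by K). Selected
#' controls (screened unaffected) weight by `1 - penetrance`; unselected
#' population controls simply have the population frequencies.
#'
#' @inheritParams solve_penetrances
#' @param penetrances vector `c(f0,f1,f2)` as from [solve_penetrances()].
#' @param controls_selected `TRUE` for screened-unaffected controls, `FALSE`
#'   for unselected population controls.
#' @return list with `case_geno`, `control_geno` (length-3 frequencies of
#'   0/1/2 risk-allele copies), `case_af`, `control_af`.
#' @export
group_frequencies <- function(penetrances, raf, controls_selected = FALSE) {
  stopifnot(length(penetrances) == 3L, all(penetrances >= 0),
            all(penetrances <= 1), raf > 0, raf < 1)
  q <- 1 - raf
  g <- c(q^2, 2 * raf * q, raf^2)
  K <- sum(g * penetrances)
  if (K <= 0) stop("model has zero prevalence; case frequencies undefined")
  case_geno <- g * penetrances / K
  control_geno <- if (controls_selected) g * (1 - penetrances) / (1 - K) else g
  list(case_geno = unname(case_geno), control_geno = unname(control_geno),
       case_af = unname(case_geno[3] + case_geno[2] / 2),
       control_af = unname(control_geno[3] + control_geno[2] / 2))
}

#' Analytic power of the case-control association test
#'
#' Computes the non-centrality parameter of the 1-df allelic chi-square test
#' (or the 2-df genotypic test) from the expected case and control allele
#' (genotype) frequencies under the penetrance model, and evaluates the
#' non-central chi-square tail beyond the central critical value at `alpha`.
#' For the allelic test,
#' `NCP = (p_case - p_ctrl)^2 / [ pbar (1 - pbar) (1/(2 n_cases) + 1/(2 n_controls)) ]`
#' with `pbar` the count-weighted mean allele frequency.
#'
#' @inheritParams solve_penetrances
#' @param n_cases,n_controls numbers of individuals (alleles are 2 per person).
#' @param alpha significance level.
#' @param controls_selected see [group_frequencies()].
#' @param test `"allelic_1df"` (default) or `"genotypic_2df"`.
#' @return list of class `power_result`: penetrances, group genotype and allele
#'   frequencies, `ncp`, `df`, `critical`, `power`.
#' @examples
#' allelic_power(0.05, 0.05, 1.65, 3, n_cases = 1353, n_controls = 6800,
#'               alpha = 5e-8)$power
#' @export
allelic_power <- function(prevalence, raf, grr_het, grr_hom,
                          n_cases, n_controls, alpha = 5e-8,
                          controls_selected = FALSE,
                          test = c("allelic_1df", "genotypic_2df")) {
  test <- match.arg(test)
  stopifnot(n_cases >= 1, n_controls >= 1, alpha > 0, alpha < 1)
  f <- solve_penetrances(prevalence, raf, grr_het, grr_hom)
  fr <- group_frequencies(f, raf, controls_selected)
  if (test == "allelic_1df") {
    pc <- fr$case_af; pm <- fr$control_af
    pbar <- (2 * n_cases * pc + 2 * n_controls * pm) / (2 * (n_cases + n_controls))
    ncp <- (pc - pm)^2 /
      (pbar * (1 - pbar) * (1 / (2 * n_cases) + 1 / (2 * n_controls)))
    df <- 1L
  } else {
    pbar_g <- (n_cases * fr$case_geno + n_controls * fr$control_geno) /
      (n_cases + n_controls)
    keep <- pbar_g > 0
    ncp <- sum(n_cases * (fr$case_geno[keep] - pbar_g[keep])^2 / pbar_g[keep]) +
      sum(n_controls * (fr$control_geno[keep] - pbar_g[keep])^2 / pbar_g[keep])
    df <- 2L
  }
  critical <- stats::qchisq(alpha, df = df, lower.tail = FALSE)
  power <- stats::pchisq(critical, df = df, ncp = ncp, lower.tail = FALSE)
  structure(list(penetrances = f, case_geno = fr$case_geno,
                 control_geno = fr$control_geno,
                 case_af = fr$case_af, control_af = fr$control_af,
                 ncp = ncp, df = df, critical = critical, alpha = alpha,
                 power = power, test = test),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("%s power: %.4f (NCP %.3f, df %d, critical %.3f at alpha %.3g)\n",
              x$test, x$power, x$ncp, x$df, x$critical, x$alpha))
  cat(sprintf("  penetrances f0/f1/f2 = %.4f/%.4f/%.4f; case AF %.4f, control AF %.4f\n",
              x$penetrances[1], x$penetrances[2], x$penetrances[3],
              x$case_af, x$control_af))
  invisible(x)
}

#' Smallest detectable heterozygote genotypic relative risk
#'
#' Bisection on the heterozygote GRR until the analytic power of the allelic
#' test equals `target_power` (|power - target| < 1e-6). The homozygote GRR is
#' either a fixed number or a function of the heterozygote GRR (e.g.
#' `function(r) r^2` for a multiplicative model).
#'
#' @inheritParams allelic_power
#' @param target_power target power in (alpha, 1).
#' @param grr_hom fixed homozygote GRR, or a function of the heterozygote GRR.
#' @param interval search bracket for the heterozygote GRR.
#' @return list with `grr_het`, `grr_hom`, achieved `power`.
#' @export
detectable_grr <- function(target_power, prevalence, raf, grr_hom,
                           n_cases, n_controls, alpha = 5e-8,
                           controls_selected = FALSE,
                           interval = c(1 + 1e-9, 50)) {
  stopifnot(target_power > alpha, target_power < 1)
  hom <- if (is.function(grr_hom)) grr_hom else function(r) grr_hom
  pow <- function(r) allelic_power(prevalence, raf, r, hom(r),
                                   n_cases, n_controls, alpha,
                                   controls_selected)$power
  lo <- interval[1]; hi <- interval[2]
  f_lo <- pow(lo) - target_power
  # shrink the upper bracket into the feasible region (penetrances <= 1)
  repeat {
    f_hi <- tryCatch(pow(hi) - target_power, error = function(e) NA_real_)
    if (!is.na(f_hi) || hi <= lo * (1 + 1e-9)) break
    hi <- lo + (hi - lo) * 0.9
  }
  if (is.na(f_hi) || f_lo * f_hi > 0)
    stop("detectable_grr: no bracketing root in [", lo, ", ", hi,
         "]; power range [", format(f_lo + target_power), ", ",
         if (is.na(f_hi)) "infeasible" else format(f_hi + target_power), "]")
  # bisect on power itself: power is strictly increasing in the GRR here
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- pow(mid) - target_power
    if (abs(fm) < 1e-6) break
    if (fm < 0) lo <- mid else hi <- mid
  }
  list(grr_het = mid, grr_hom = hom(mid), power = fm + target_power)
}
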