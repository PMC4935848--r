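---
title: "Methods: pooled exome screening for low-frequency risk variants"
author: "poolscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled exome screening for low-frequency risk variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

## The design this package models

poolscreen implements the analysis chain of a case-only pooled exome
sequencing screen, the design used to hunt low-frequency (minor allele
frequency 1–5%), moderate-to-large-effect risk variants in founder
populations: DNA from affected individuals is sequenced in pools (here, a
hundred cases in ten pools of ten at a mean depth of ~220x), pooled
minor-allele frequencies are estimated from read counts, candidates enriched
against several reference panels are selected through a filter cascade, the
survivors are individually genotyped in two validation rounds, and the final
variants are tested for case-control association against a large unselected
population reference plus quantitative-trait association. The package also
contains the discrete-trait power model used to size such designs, and a
synthetic-data generator that emulates every data stream so that the whole
chain is testable end to end without any individual-level data.

## Pooled MAF estimation

For one pool, the estimator is the proportion of reads carrying the minor
allele among all reads covering the position. Across pools the package uses
the read-weighted form

$$\hat p = \frac{\sum_j a_j}{\sum_j (r_j + a_j)},$$

with $a_j$, $r_j$ the alt and ref reads of pool $j$. This matches the verbal
definition "proportion of reads ... in the total amount of reads" literally;
the alternative (mean of per-pool proportions) differs when depths are
unequal. The estimator is unbiased for the pooled-sample allele frequency
only under equal sample representation within a pool; the generator exposes a
Dirichlet concentration parameter precisely so that tests can violate that
assumption and observe the variance inflation.

Zero-depth pools are undefined (`NA`), never `0` — a position without
coverage carries no evidence of absence.

**Pool presence.** Published descriptions of such screens leave "present in a
pool" caller-defined and unrecoverable. The package's explicit stand-in: at
least 2 alt reads *and* at least 1% alt read fraction (`call_pool_presence`,
both thresholds configurable). The fraction gate stops high-depth pools from
calling presence out of sequencing error; the count gate stops single-read
artefacts.

## The filter cascade

`run_cascade()` applies, in order: mapping quality ≥ 20 and depth ≥ 10x in at
least one pool; functional class in {missense, nonsense, splice}; presence in
≥ 2 case pools; the technical-control pool rule; enrichment ratio ≥ 1.5
against every available panel; gene blacklists and the dbSNP "suspected"
flag; and an alternative-source check for variants no panel reports. Two
auxiliary strategies (linkage-peak regions, reference-allele-minor variants)
and a manual include list are unioned afterwards. Every stage is a pure
predicate, so the cascade is idempotent and the stage order of the pure
stages cannot change the final set — both are tested properties.

Boundary readings are literal: "over five" technical-control pools means ≥ 6
excluded, "less than two" means 0–1, "at least two" case pools means ≥ 2,
"over two" means ≥ 3. Where the verbal rules are silent the package decides
once and documents here:

* Variants in 2–5 technical-control pools pass that stage without the
  frequency-panel MAF sub-filter (the two quoted rules cover only the > 5 and
  < 2 branches); the enrichment stage still applies downstream.
* A variant absent from the frequency panel passes the MAF ≤ 0.05 sub-filter
  — absence of evidence of commonness is not evidence of commonness, and the
  enrichment stage judges such variants anyway.
* "MAF higher than or similar to" the case MAF, for alternative-source
  checks, is operationalised as a case/source ratio below the same 1.5
  enrichment threshold, keeping one threshold vocabulary.
* Enrichment against a panel reporting frequency 0 is $+\infty$ (passes any
  finite threshold); 0/0 is undefined and cannot demonstrate enrichment, so
  it fails that comparison.
* Near-cut-off rescues are a manual include list — an explicit file, not a
  hidden heuristic.
* The minor-allele orientation tie at exactly 0.5 breaks toward the alt
  allele.

## Genotype validation and association

The association layer mirrors PLINK's basic allelic analysis: a 1-df Pearson
chi-square without continuity correction on the 2×2 allele-count table (two
alleles per person), odds ratio as the cross-product $ad/bc$, and a Woolf
confidence interval $\exp(\log \mathrm{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$.
Zero cells flag the OR as undefined by default; a Haldane 0.5 correction is
available by argument, never silently.

A caution about reconstructing ORs from published summary tables: the OR of
an allele-count table depends only on the two MAFs, so counts rebuilt from
MAFs printed to three decimals can shift the OR by ~0.01 — reconstructions
should be read at that precision, whatever the cohort size.

Hardy-Weinberg equilibrium uses the exact conditional test (summing the
probabilities of heterozygote counts no more probable than the observed one,
given the allele counts), not the chi-square approximation, which is invalid
at the low minor-allele counts this design targets. The distribution is built
by a log-space ratio recurrence and verified in the tests against a direct
log-factorial enumeration for every table with up to 200 individuals. The
HWE exclusion level in controls defaults to p < 0.05 (the motivating design
reports exclusions without stating a level) and is configurable.

Other QC rules: differential missingness is a 2×2 chi-square when all
expected cells reach 5, else Fisher's exact test; samples failing more than
2 otherwise-successful assays are removed (assays that failed globally count
against nobody); duplicate-run concordance counts jointly observed pairs
only, and any sample with a discordant pair is excluded. Round-two selection
keeps OR ≤ 0.65 or ≥ 1.3, inclusive on both boundaries, after removing
monomorphic variants.

When study controls are merged with a mixed-sex population reference,
X-chromosome variants are excluded (pooling male and female X genotype
counts would distort allele frequencies); autosomal allele frequencies are
not assumed to differ between sexes, so autosomal variants merge by simple
count addition. Reference panels contribute genotype counts; if only
frequencies are available, counts are reconstructed as `round(2 N f)` — a
documented approximation.

Linkage disequilibrium between two variants is estimated from unphased
genotypes by EM over the four haplotype frequencies (only the double
heterozygote is phase-ambiguous), reporting $r^2 = D^2/(p_A q_A p_B q_B)$
and $D' = D/D_{max}$.

## The power model

`solve_penetrances()` inverts the prevalence constraint of a single
bi-allelic locus in Hardy-Weinberg proportions:

$$f_0 = \frac{K}{q^2 + 2pq\,R_{het} + p^2 R_{hom}}, \qquad
f_1 = R_{het} f_0, \qquad f_2 = R_{hom} f_0,$$

rejecting models where any penetrance exceeds 1. Case genotype frequencies
weight the population frequencies by penetrance (normalised by $K$);
screened-unaffected controls weight by $1 - f_g$; unselected population
controls keep the population frequencies. The 1-df allelic test's
non-centrality parameter is

$$\lambda = \frac{(p_{case} - p_{ctrl})^2}
{\bar p (1-\bar p)\left(\frac{1}{2N_{case}} + \frac{1}{2N_{ctrl}}\right)},$$

with $\bar p$ the count-weighted mean allele frequency, and power is the
non-central $\chi^2_1(\lambda)$ tail beyond the central critical value
(evaluated by R's `pchisq`, accurate to well below $10^{-10}$ here). A 2-df
genotypic variant of the calculation is provided but the headline numbers
use the allelic test. `detectable_grr()` inverts power over the heterozygote
GRR by bisection to $|power - target| < 10^{-6}$, shrinking the upper
bracket into the feasible (penetrance ≤ 1) region first.

For the reproduced design numbers the controls are treated as **unselected**,
since roughly 6118 of the ~6800 controls come from a population reference
with no phenotype screening; the selected-controls variant is one flag away.
Under that reading the 1353-case design reaches power ≈ 0.816 for GRR
1.65/3 at risk-allele frequency 0.05 and genome-wide α = 5×10⁻⁸, and the
detectable heterozygote GRR at frequency 0.01 with homozygote GRR 5 is
≈ 2.518.

## What the generator emulates, and what it does not

The stated world of `run_config()` defaults: 200 variants with population
frequencies uniform in [0.01, 0.05]; one planted causal missense variant at
frequency 0.02 with genotypic relative risks 3/9; 1300 genotyped cases and
700 screened controls, of whom 100 cases are pooled 10×10 and sequenced at
mean depth 220x (negative-binomial dispersion 0.05 — per-pool average depths
in such screens range roughly 95x–277x, and the within-pool law is a free
choice); a 6000-sample mixed-sex (43% male) unselected reference cohort; a
frequency-only panel drifted on the logit scale (σ = 0.05); a
technical-control panel of 100 independent samples pooled and sequenced
identically; per-read error 0.001; genotyping missingness 0.02 and error
0.001.

The planted causal frequency 0.02 is the mid-band choice: the screen's
sensitivity genuinely collapses toward both band edges — at 1% the pooled
estimate from 100 cases is too noisy to clear the 1.5× enrichment ratio
reliably, and above ~3% a real variant is present in many technical-control
pools and the "> 5 pools" cut removes it. That band-pass behaviour is a
property of the published filter, not of this implementation, and the
replicate test documents it: the planted variant survives the cascade and
ranks first in the merged association in about 80% of seeded replicates.

Deliberately not emulated: read-level artefacts (alignment, strand,
context-dependent error), indels and multi-allelic records (split upstream,
one row per alt allele), haploid male X dosage (sex is recorded and X
variants are excluded from merged analyses, which makes the dosage moot),
population substructure within the reference, and multi-locus genetic
architectures (one causal variant per run, matching the single-locus power
model). A green end-to-end test therefore establishes that the statistical
machinery is correct under the stated world — not that the design is robust
to artefacts it does not model.

Randomness: one master seed; every stage derives a child stream by hashing
its stage name (`stage_seed`), so adding a stage never perturbs another's
draws, and identical configurations reproduce byte-identical output files.

## Numerical notes

* HWE exact probabilities are accumulated in log space from the ratio
  recurrence and normalised once; the tie comparison uses a $1 + 10^{-10}$
  relative guard, so enumeration and recurrence agree to < 10⁻⁹ over all
  ~7×10⁵ tables with n ≤ 200.
* `allelic_chisq` accepts non-integer counts so tables can be rebuilt from
  published frequencies.
* The EM for haplotype frequencies starts at linkage equilibrium, iterates
  the single ambiguous class, and stops at a 10⁻¹⁰ haplotype-frequency
  change, erroring (with the iteration count) if 1000 iterations do not
  converge.
* Penetrance feasibility allows a 10⁻¹² tolerance at the f = 1 boundary
  before declaring a model infeasible.
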