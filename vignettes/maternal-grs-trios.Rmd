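---
title: "Testing maternal genetic effects with parental risk-score contrasts"
author: "triogrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing maternal genetic effects with parental risk-score contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triogrs)
```

## The design

A *maternal genetic effect* is an association between the mother's genotype
and her child's disease risk that acts through the intrauterine environment,
independently of the alleles the child inherits. Congenital conotruncal
heart defects (CTDs) are a natural target: maternal hypertension, type 2
diabetes and obesity are established epidemiological risk factors, so a
maternal *genetic predisposition* to those conditions — even without the
overt phenotype — could plausibly raise offspring risk.

With case-parent trios (an affected child plus both biological parents)
there is no external control group, and no off-the-shelf method for testing
a *weighted multi-SNP* maternal score in a trio likelihood. The design
implemented here sidesteps that: mothers of affected children serve as
"cases" and the fathers as "controls". Under random mating and no maternal
genetic effect, the two parents of an affected child are exchangeable with
respect to any genetic score that acts only through the mother, so their
score distributions coincide. A systematic maternal excess is evidence of a
maternal genetic effect.

Each parent's genetic risk score (GRS) for condition $k$ is the weighted
allele count

$$ S_k = \sum_{i \in \text{panel}_k} w_i \, g_i, \qquad g_i \in [0, 2], $$

with published per-allele weights $w_i > 0$ oriented to the risk allele,
and a combined score $S = S_{\mathrm{HTN}} + S_{\mathrm{OBESITY}} +
S_{\mathrm{T2D}}$ (exact additivity is enforced by construction). Dosages
may be fractional because genotypes are typically imputed. The default
panel mirrors the published score set: 31 hypertension, 30 obesity and 46
type-2-diabetes common SNPs with no SNP shared between conditions.

Two complementary contrasts are computed per condition:

* **Mean contrast.** An unpaired, equal-variance Student's *t* test of
  mothers versus fathers. Shapiro–Wilk normality is checked in each group
  first; if either group rejects at $\alpha = 0.05$ and all scores are
  positive, both groups are log-transformed before testing. The paired
  alternative (pairing spouses within trios) would also be defensible;
  the unpaired test was chosen because the parents are genetically
  unrelated, making independence the natural assumption.
* **Threshold contrast.** Scores are dichotomized at the nearest-rank
  empirical percentile of the *fathers'* distribution (levels 0.95, 0.90,
  0.75 by default — the top 5th/10th/25th percentiles), "high" meaning
  strictly greater than the cutoff. The resulting 2×2 table (mothers as
  cases) is tested with the conventional two-sided Fisher exact test, and
  the association is summarized by the sample odds ratio
  $\mathrm{OR} = ad/bc$ with a Woolf (logit) 95% CI. The threshold form
  exists because a maternal effect may only be visible in the extreme tail
  of genetic liability; where that threshold lies is unknown, hence the
  three arbitrary levels.

Subgroup re-analyses (per recruiting cohort, excluding mothers with overt
phenotypes — preeclampsia, medicated hypertension, pregestational diabetes —
or restricting to tetralogy-of-Fallot trios) rerun the identical machinery
on the filtered trios. Cutoffs are always recomputed from the *subgroup's*
fathers, never inherited from the full cohort: each subgroup analysis is a
self-contained instance of the design.

## Conventions and numerical choices

* **Nearest-rank percentile.** The $q$-quantile of $n$ fathers is the
  $\lceil nq \rceil$-th order statistic: always an observed score,
  deterministic under ties. With continuous scores this leaves
  $n - \lceil nq \rceil$ fathers above the cutoff (35 of 700 at $q=0.95$).
* **Fisher two-sidedness.** The two-sided $p$ sums all hypergeometric table
  probabilities not exceeding the observed one (the classical convention,
  as implemented in `stats::fisher.test`). The odds ratio reported is the
  sample cross-product ratio, *not* the conditional MLE.
* **Zero cells.** The Haldane–Anscombe correction (+0.5 to every cell)
  is applied to the OR and its CI — never to the Fisher $p$ — only when a
  cell is zero.
* **Allele alignment.** Genotype carriers (VCF) count the ALT allele; each
  SNP is flipped ($g \mapsto 2-g$) when the counted allele is the weight
  table's non-effect allele. Any allele-pair mismatch, including a
  strand-ambiguous A/T or C/G SNP whose labels disagree, is a hard error:
  silent strand complementing corrupts risk-allele orientation and is never
  attempted.
* **Missing genotypes.** The default policy imputes a missing dosage by the
  mean oriented dosage of that SNP *within the same parental role*, which
  preserves sample size without biasing the mother–father contrast;
  `drop_sample` and `score_available` are available alternatives. Panel
  SNPs that are entirely unavailable are simply excluded from the weight
  table handed to the engine (scores are raw weighted sums; nothing is
  rescaled by SNP count).
* **Bonferroni screen.** Single-SNP maternal-effect $p$-values (consumed
  from upstream trio GWAS meta-analysis, never recomputed here) are
  classified against $0.05/n_k$ per condition panel: significant at
  $p \le 0.05/n_k$ (the exact quotient; the one-significant-digit value is
  display only), "suggestive" strictly between, null at $p \ge 0.05$.
* **Shapiro–Wilk bounds.** The W statistic is undefined above $n = 5000$;
  larger groups are thinned to 5000 evenly spaced order statistics.
  Zero-range groups have no defined W and skip the transform trigger.
* **r×c cohort tables.** Between-cohort Fisher tests of descriptive
  variables enumerate exactly up to 200 observations and switch to a
  fixed-seed Monte-Carlo estimate (100,000 draws) above that, so results
  are reproducible at any size. Percentages use the variable's
  non-missing ("unknown"-excluded) total within each cohort, uniformly —
  published cohort tables are not always consistent about this, and a
  single rule was preferred to row-by-row mimicry.

## What the simulator emulates

`simulate_trios()` makes the whole design measurable without any real
genotypes. Its generative model:

1. **Panel.** Effect-allele frequencies uniform in (0.1, 0.9) — all SNPs
   comfortably common — and gamma-distributed weights whose per-condition
   means (0.574, 0.127, 0.096 for HTN/obesity/T2D) put the simulated score
   means at the study scale (≈17.8 / 3.8 / 4.4, combined ≈26). These
   scales were fixed once, from the published score magnitudes, before any
   operating characteristics were measured.
2. **Parents.** Independent Hardy–Weinberg genotypes at every SNP
   (random mating, no assortative mating, no linkage disequilibrium, no
   population stratification).
3. **Child.** One allele per parent per SNP (Mendelian transmission), so
   $E[g_c \mid g_m, g_f] = (g_m + g_f)/2$.
4. **Affection.** Logistic liability through the mother only:
   $P(\text{affected}) = \operatorname{expit}(\alpha + \beta_m z_m)$ with
   $z_m$ the mother's combined GRS standardized by the population moments
   $\mu = \sum 2 f_i w_i$, $\sigma^2 = \sum w_i^2\, 2 f_i (1 - f_i)$;
   or, in threshold mode,
   $\operatorname{expit}(\alpha + \beta_m \mathbf{1}[S_m > \text{pop.
   quantile}])$. The threshold is a *population* quantile (normal
   approximation $\mu + \sigma\, \Phi^{-1}(q)$), so the simulated threshold
   effect is a property of the model, not of a finite sample; the level is
   a free parameter because the real threshold, if any, is unknown.
5. **Intercept.** $\alpha$ is solved by bisection (interval tolerance
   $10^{-10}$) so the marginal prevalence equals the 1% congenital-heart-
   defect live-birth frequency. In linear mode the marginal probability
   integrates the logistic over the standard normal law of $z_m$; with 107
   independent SNPs the central-limit approximation error is orders of
   magnitude below the simulation noise the package ever resolves.
6. **Ascertainment.** Only affected-child trios are kept (rejection
   sampling) until the target count is reached. When $\beta_m = 0$ the
   affection probability is constant, so the conditional genotype law
   equals the population law and trios are drawn directly — an exact
   shortcut, not an approximation. Fathers are always drawn from the
   population law: ascertainment acts only through the mother, which is
   precisely the design's null symmetry.

An optional per-genotype missingness rate and study-like phenotype fields
(defect subtypes, preeclampsia, medicated hypertension, pregestational and
gestational diabetes at roughly the published frequencies) make every
subgroup filter exercisable. A deliberate omission mirrors the design's
known blind spot: the default model has *no* direct child-genotype effect,
because the trio contrast cannot separate maternal from inherited effects;
the simulator keeps the confound explorable rather than baked in.

What passing simulation tests does **not** show about real data: robustness
to linkage disequilibrium within the panel, to population stratification or
assortative mating (all of which can shift parental score distributions),
or to differential genotyping error between mothers and fathers.

## Operating characteristics

`operating_characteristics()` runs the full scoring-plus-contrast pipeline
over replicate simulated cohorts and reports empirical rejection rates of
the percentile OR test and the mean contrast, the mean OR, and the
fraction of replicates with a maternal mean excess. The package's own
checks run it at the study scale — 700 trios, the 107-SNP panel, 1000 null
replicates and 200 replicates per effect size on the grid
$\beta_m \in \{0, 0.3, 0.6, 1\}$ — sizes chosen to pin rates to about
±1–2 percentage points.

One structural property deserves emphasis. The 95th-percentile OR test is
*conservative by construction*: the cutoff is estimated from the same
fathers that enter the table, which fixes the father-high cell at
$n - \lceil 0.95 n \rceil$ exactly, while Fisher's test treats both margins
as free; on top of that the exact test is conservative through discreteness.
The measured null rejection rate therefore falls *below* the nominal 5%
level (the acceptance harness reports the measured value). Type-I error is
controlled — the test never over-rejects — at some cost in power, which is
the usual trade-off of exact conditional tests.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_trios(sim_config(n_trios = 721, beta_m = 0.6, seed = 2024))
roles <- parent_roles(sim$trios)
grs <- compute_grs(subset_samples(sim$dosages, names(roles)),
                   sim$weights, roles)
fit <- grs_contrast(grs, sim$trios)
fit
coef(fit)                                # odds ratios, condition@level
grs_contrast(grs, sim$trios,
             subgroup_spec(ctd_subtype = "ToF"))   # subtype re-analysis
```

The same analysis runs end to end from one configuration with
`run_pipeline()`, which writes every stage's TSV plus a JSON manifest with
file checksums; identical configuration and seed reproduce byte-identical
tables.

## Limitations

* The contrast detects maternal effects only through the scored panel with
  its fixed published weights; a different SNP set or reweighting might be
  more predictive of offspring risk, and nothing here re-estimates weights.
* Offspring genotype is not adjusted for — the design cannot separate a
  maternal genetic effect from an inherited effect of the same alleles.
* Single-SNP screening consumes externally computed maternal-effect
  p-values; the underlying trio GWAS is out of scope.
* The cohort-table module reproduces the *rule* (uniform non-missing
  denominators), not every idiosyncrasy of published tables.
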