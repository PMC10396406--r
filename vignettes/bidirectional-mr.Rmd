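---
title: "Bidirectional two-sample MR: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional two-sample MR: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimr)
```

# The problem and the model

Mendelian randomization treats genetic variants as instrumental
variables: because alleles are assigned at conception, a SNP that
robustly alters an exposure $X$ can identify the causal effect $\theta$
of $X$ on an outcome $Y$ free of the confounding that plagues
observational regression — provided the instrument assumptions hold
(association with $X$; independence from confounders; no effect on $Y$
except through $X$). In the two-sample design the SNP–exposure
associations $(\hat\beta_{Xj}, se_{Xj})$ and SNP–outcome associations
$(\hat\beta_{Yj}, se_{Yj})$ come from different studies; "pseudo"
two-sample means the two studies partially overlap, which re-introduces
a weak-instrument bias toward the confounded association (winner's
curse). Bidirectional means the whole analysis is run in both
directions, $X \to Y$ and $Y \to X$, to probe the direction of
causation.

`bimr` implements this design end to end. The estimator layer is the
package's own code throughout (closed-form weighted least squares,
interpolated weighted median, hat-matrix influence measures); standard
steps around it (BH correction, OLS for the observational models) call
base R.

## Estimators

With weights $w_j = 1/se_{Yj}^2$:

* **IVW**: $\hat\theta = \sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj} \big/
  \sum_j w_j \hat\beta_{Xj}^2$, the weighted regression of outcome on
  exposure betas through the origin, identical to the inverse-variance
  weighted mean of the per-SNP Wald ratios $\hat\beta_{Yj}/\hat\beta_{Xj}$
  weighted by $\hat\beta_{Xj}^2/se_{Yj}^2$. Heterogeneity:
  $Q = \sum_j w_j(\hat\beta_{Yj} - \hat\theta\hat\beta_{Xj})^2$ and
  $I^2 = \max(0, (Q - (J-1))/Q)$.
* **Multiplicative random effects**: the reported IVW standard error is
  the fixed-effect one times $\phi = \max(1, \sqrt{Q/(J-1)})$. The
  truncation at 1 means between-SNP heterogeneity can only widen, never
  narrow, the interval; this makes the test slightly conservative when
  there is no heterogeneity, which we consider the right failure mode.
* **MR-Egger**: the same weighted regression with a free intercept
  $\beta_0$; a nonzero intercept is average directional pleiotropy and
  its two-sided p-value the pleiotropy test. The multiplicative scale is
  applied to both coefficient SEs with $J-2$ degrees of freedom in $Q$,
  for consistency with the IVW convention. Exposure betas are
  sign-oriented positive before fitting (the intercept is only
  identified up to this orientation). $I^2_{GX}$ — the weighted-variance
  statistic of the $\hat\beta_{Xj}$ relative to their standard errors —
  is attached to quantify regression-dilution (NOME-violation) bias;
  values near 1 mean the Egger slope is essentially undiluted.
* **Weighted median**: per-SNP ratios ordered ascending with normalized
  weights $w_j \propto 1/se(\hat\theta_j)^2$; the estimate interpolates
  the ratio at standardized cumulative weight $s_j = \sum_{i\le j} w_i -
  w_j/2 = 1/2$. It is consistent while valid instruments carry more
  than half the total weight. Its SE comes from a parametric bootstrap
  (default 1000 draws of $\hat\beta_{Xj}, \hat\beta_{Yj}$ around their
  observed values); whether an analytic or bootstrap SE is "the"
  convention is genuinely open in the field, and we chose the bootstrap
  because it needs no extra approximation and is exactly reproducible
  under the declared seed. Instruments are sorted by variant ID before
  sampling so the result cannot depend on row order.
* **Inference** uses normal quantiles, not $t$: instrument counts in
  this design are moderate (tens of SNPs) and the convention must be
  pinned for reproducibility; the choice is visible in one place
  (`two_sided_p`) and easily revisited.

## Instrument construction and harmonization

Instruments are the genome-wide significant hits (strict
$p < 5\times10^{-8}$) pruned by greedy LD clumping: rank by p-value
(ties: position, then ID), keep the best, discard everything on the same
chromosome within ±250 kb with $r^2 > 0.1$ against it, repeat. Pairs
absent from the supplied LD table count as unlinked — LD tables are
sparse in practice, and assuming $r^2 = 0$ for unlisted pairs is the
only convention that does not silently discard instruments; a pair at
exactly the threshold is retained.

Harmonization joins the two studies on rsID (not position — published
instrument lists are rsID lists; positions serve only the clumping
window), after orienting every exposure beta trait-increasing (flip
sign, swap alleles, invert eaf). Swapped allele labels flip the outcome
beta; strand-complement labels are relabelled first. Palindromic SNPs
(A/T, C/G) are strand-ambiguous: when either study's effect-allele
frequency is missing or falls in the window [0.42, 0.58] they are
dropped; otherwise the strand is inferred from frequency agreement.
The window is configurable; the rule is the conservative standard
practice, adopted because the alternative (keeping all palindromes)
risks silently reversed instruments.

## Sensitivity battery

* **Cook's distance** on the weighted regression underlying IVW
  ($p = 1$, through the origin) or Egger ($p = 2$), flagged above the
  conventional $4/J$ (configurable), with the estimator suite re-run on
  the reduced set. Funnel coordinates (ratio vs precision) are exported
  for plotting.
* **Confounder screen**: every (SNP, confounder) pair tested by simple
  linear regression, Benjamini–Hochberg applied across all pairs
  jointly at FDR 0.05, any variant with a rejected pair excluded in a
  sensitivity re-fit. The screen is deliberately unadjusted — it asks
  whether the instrument is associated with the confounder at all.
* **Sample-overlap / winner's-curse bias**: the standard approximation
  $\mathrm{bias} = o \cdot b_{conf}/\bar F$ for overlap fraction $o$,
  confounded observational association $b_{conf}$ and mean instrument
  F; the induced type-1 inflation is
  $P(|Z + \mathrm{bias}/se| > z_{1-\alpha/2})$. This is a documented
  first-order approximation for reasoning about direction and rough
  magnitude, not a claimed exact correction; the constant is surfaced
  in the report object.
* **Split-sample MR**: a seeded permutation splits the cohort into
  halves of $\lceil n/2\rceil$ and $\lfloor n/2\rfloor$ (378 877
  individuals split 189 439 / 189 438); per-SNP associations are
  re-estimated within each half, MR runs A-on-B and B-on-A, and the two
  estimates are pooled by fixed-effect inverse-variance meta-analysis.
  Because discovery and analysis never share individuals, the pooled
  estimate is free of winner's curse.
* **Reporting**: adiposity-style exposures are standardized to SD units
  using the population-SD convention (divide by $n$, not $n-1$ —
  negligible at study scale but pinned so tests are exact and the
  transform is idempotent). Positively skewed outcomes are analysed on
  natural logs and coefficients (expressed in $100 \times \ln$ units)
  reported as exact percent differences $100(e^{b/100}-1)$ via
  `percent_difference()`;
  count-like traits with a floor at zero use $\ln(x+1)$ with the offset
  recorded. Bonferroni thresholds are `level / n_tests` with the test
  count equal to the number of exposure–outcome pairs across both
  directions (a 5×2 forward plus 2×3 reverse grid gives 16 tests, so
  0.05 becomes 0.003125); thresholds are shown alongside raw p-values
  rather than rescaling the p-values themselves.

# The synthetic-data generator

`simulation_config()` / `simulate_cohorts()` define the study
conditions under which the package tests itself:

$$U \sim N(0,1) + \textstyle\sum_{c} d\, G_c, \qquad
X = \textstyle\sum_j \gamma_j G_j + q_U U + \epsilon_X, \qquad
Y = \theta X + \textstyle\sum_j \alpha_j G_j + r_U U + \epsilon_Y$$

with $G_j \sim \mathrm{Bin}(2, \mathrm{MAF}_j)$,
$\mathrm{MAF}_j \sim U(0.05, 0.5)$, standard normal noise, and the
first $\lfloor o \cdot n \rfloor$ individuals shared between the two
cohorts. Defaults: $J = 50$ SNPs, $n = 20\,000$ per cohort,
$\theta = 0.2$, $q_U = r_U = 0.3$, $\gamma_j \sim |N(0.08, 0.04)|$.
The effect-size scale gives per-SNP instrument z-scores around 6 at
$n = 20\,000$ — strong but not noiseless instruments, typical of a
well-powered GWAS of an anthropometric trait — and the wide spread
(sd comparable to the mean) mirrors the heavy-tailed effect-size
distributions of real instruments while keeping $I^2_{GX}$ near 0.9.
Pleiotropic effects $\alpha_j$ follow the configured regime: balanced
$N(0, 0.01^2)$, directional $N(0.02, 0.01^2)$, or correlated with
$\gamma_j$ (violating InSIDE). LD blocks copy the anchor SNP's
haplotypes with probability $\sqrt{r^2}$, so the anchor–member genotype
correlation hits the target $r^2$ (member–member pairs carry $r^4$);
block members share the anchor's MAF and sit within 100 kb, distinct
loci 1 Mb apart. Skewed outcomes are generated by exponentiating the
linear outcome, so the log-transform / percent-difference reporting
path is exercised end to end; count traits are Poisson with log link.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: realistic human LD maps and allele-frequency
spectra, imputation uncertainty, relatedness and population structure
(the simulated "principal components" are pure noise covariates that
exercise the adjustment code path, not actual structure), selection
into the cohort, and indels/multi-allelic sites. The generator is a
correctness instrument for the statistics, not a population-genetics
simulator.

# Numerical choices and degenerate inputs

* Text I/O writes doubles with 17 significant digits, so round trips
  are bit-exact; missing eaf serializes as `NA`.
* $Q = 0$ (exact fit) yields $I^2 = 0$ and zero Cook's distances rather
  than 0/0.
* `wald_ratio` refuses a zero exposure beta, and a negative one with a
  pointer to `orient_to_trait_increasing()`; `mr_fit` refuses J below
  each estimator's minimum (2 for IVW, 3 for Egger/WME) with the
  applicable fallback named. `rerun_without` degrades gracefully:
  estimators that can no longer run after exclusion are reported with
  the reason instead of erroring.
* Clump ties at equal p-value break by ascending position then
  lexicographic ID, so output is deterministic.
* Every stochastic routine (generator, bootstrap, split) takes an
  explicit seed and restores the caller's RNG stream; the pipeline is a
  pure function of (inputs, config, seed), and identical runs compare
  `identical()`.

# Test-suite problem sizes

The calibration suites run at: 200 replicates for IVW parameter
recovery and CI coverage ($J = 50$, $n = 20\,000$, $\theta = 0.2$); 500
replicates for Egger intercept calibration under balanced pleiotropy
($n = 10\,000$, $\theta = 0$ — the intercept's null) and 200 for its
power under directional pleiotropy ($n = 20\,000$, $\mu_\alpha =
0.02$); 100 replicates for the weighted-median robustness comparison
(40% invalid instruments, $\alpha \sim N(0.1, 0.02^2)$); 500 replicates
for the global-null IVW size ($n = 5\,000$). Where a suite's cohort
size is not itself part of the property being tested we use the
smallest size at which the property is comfortably in its asymptotic
regime; all seeds are fixed in the tests.

# Known limitations

* The Wald-ratio SE is first-order (ignores exposure-beta uncertainty),
  consistent with the IVW weighting; no iterative reweighting.
* No mode-based estimators, MR-PRESSO, Steiger filtering or
  multivariable MR; no LD computation from reference panels (precomputed
  $r^2$ tables only); no PLINK binary formats.
* The overlap-bias formula is an approximation for interpretation, not
  a bias correction.
* The weighted-median bootstrap resamples betas independently per SNP;
  correlated instruments (clumping leftovers above the threshold) are
  not modelled in the SE.
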