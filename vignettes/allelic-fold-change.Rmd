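---
title: "Estimating cis-regulatory effect sizes as allelic fold change"
author: "allelicfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cis-regulatory effect sizes as allelic fold change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelicfc)
```

## The model

A cis-regulatory variant acts on the chromosome copy that carries it. For a
biallelic eVariant with reference allele 0 and alternative allele 1, write
$e_0$ and $e_1$ for the expression produced by the haplotype carrying each
allele. Their ratio $\delta = e_1 / e_0$ is the *allelic fold change* (aFC),
and $s = \log_2 \delta$ is the effect size this package estimates. Because
total expression is the sum of the two haplotypic expressions, an individual
with $t \in \{0, 1, 2\}$ alternative alleles has expected expression

$$ e(t) = \left[(2 - t) + t\,\delta\right] e_0 , $$

which is linear in $t$ on the natural scale and *nonlinear* after the log
transform that is routinely applied to stabilize the multiplicative noise of
RNA-seq expression data. $s$ is zero for a null variant, changes only sign
under relabeling of the alleles, adds across independent variants on a
haplotype, and does not depend on expression level or allele frequency —
which is what makes it comparable across genes, studies and data types.

All estimates are constrained to a 100-fold ratio, $|s| \le \log_2 100
\approx 6.64$ (`AFC_CAP`): beyond that bound the data essentially say "one
haplotype is silent" and the magnitude is no longer quantifiable from
read counts.

## Estimators from total expression

Three estimators consume an expression vector and the per-individual
alternative-allele count:

* **M1** (`fit_linear_afc()`) assumes additive noise: OLS of linear-scale
  expression on $t$ gives intercept $b_0 = 2 e_0$ and slope
  $b_1 = e_0(\delta - 1)$, hence $\delta = 2 b_1 / b_0 + 1$. It is the
  fastest estimator and the correct maximum-likelihood one when noise is
  homoskedastic on the natural scale. When noise pushes
  $2 b_1/b_0 + 1 \le 0$ (strong negative effects), $\delta$ is floored at
  $1/100$, the reciprocal of the cap, so the estimator stays total; a
  non-positive intercept is reported as an undefined-baseline error.
* **M2** (`fit_nonlinear_afc()`) assumes multiplicative log-normal noise and
  minimizes $\sum_n \left(z_n - \log_2[(2 - t_n) + t_n 2^s] - \log_2
  e_0\right)^2$ over $(\log_2 e_0, s)$ with $z$ the log2 expression.
* **M3** (`fit_approx_afc()`) approximates M2 in linear time: it forms four
  candidate $\delta$ values — the three pairwise ratios of per-genotype-class
  geometric means, $m_2/m_0$, $(2 m_1/m_2 - 1)^{-1}$, $2 m_1/m_0 - 1$, and
  $2^{2 c_1}$ from the log-scale regression slope $c_1$ (for a weak effect,
  log expression is nearly linear in $t$ and the slope approaches $s/2$) —
  and keeps the candidate with the lowest residual variance under the
  log-scale model. Candidates needing an absent genotype class, or with a
  non-positive ratio, are skipped, which keeps the estimator usable in
  cohorts that lack rare homozygotes.

```{r estimators}
set.seed(1)
t <- rbinom(200, 2, 0.6)
y <- ((2 - t) + t * 2^1.5) * 40 * 10^rnorm(200, 0, 0.17)
fit_linear_afc(y, t)$estimate$log2_afc
fit_nonlinear_afc(log2(y), t)$log2_afc
fit_approx_afc(log2(y), t)$log2_afc
```

### Numerical choices in M2

Given $s$, the intercept $\log_2 e_0$ enters linearly, so it is profiled out
in closed form and the optimization is a one-dimensional bounded search in
$s \in [-\log_2 100, \log_2 100]$, solved by Brent's method on
per-genotype-class sufficient statistics ($O(1)$ objective evaluations after
one pass over the data). The search is initialized at the M3 estimate and
the returned solution is never worse than that initialization, so the M2
residual variance is bounded above by every M3 candidate's; an
initialization that already fits exactly (noiseless data) is returned
unchanged, which makes M2 exact, not just accurate, on noise-free input.
Ties in the M3 candidate selection are broken by candidate index (1 through
4) so output is deterministic. Individuals with a missing genotype or a
non-finite expression value are dropped pairwise; fits require at least two
genotype classes, and classes with fewer than three members trigger a
warning but are used.

## Estimation from allele-specific expression

In individuals heterozygous for the eVariant, reads at phased heterozygous
transcribed SNPs measure each haplotype's expression directly.
`aggregate_haplotypic_counts()` sums the allelic counts over the gene's
sites into one $(c_0, c_1)$ pair per individual, using the phase of each
site relative to the eVariant; `afc_from_phased_counts()` then estimates
$\delta$ as the median of $c_{1,n}/c_{0,n}$. Pairs with haplotypic coverage
$c_0 + c_1 < 10$ are dropped and at least five individuals must remain
(both thresholds are arguments), otherwise the result is flagged
not-estimable rather than guessed.

Zero-denominator ratios are kept as $+\infty$ rather than dropped or
pseudocounted: the median is robust to a minority of infinite ratios, and if
the majority of individuals have a silent reference haplotype the infinite
median is exactly the situation the $\pm\log_2 100$ cap is for. Even-sized
cohorts use the midpoint of the two central ratios on the ratio scale.

Without phase information only the magnitude is identified
(`afc_magnitude_unphased()`, the median of $|\log_2 c_1/c_0|$), and that
magnitude is biased upward when the true effect is small, because count
noise alone produces nonzero allelic imbalance in every individual.

## Covariate correction

Expression confounders (latent expression factors, genotype principal
components) are removed in two steps before eQTL-based estimation: a joint
linear fit $z = \mu + \alpha C + \beta t + \varepsilon$ discards every
covariate whose 95% t-interval covers zero (`prune_covariates()`), then the
model is refit with the surviving covariates and only $\alpha C$ is
subtracted (`correct_expression()`) — the genotype term is estimated but
deliberately left in the data, so the regulatory signal is untouched and the
correction is idempotent. Pruning uses the single joint regression rather
than covariate-by-covariate marginal tests because the correction itself is
joint; all covariate rows are treated identically. For M1, which needs
linear-scale input, corrected log2 expression is exponentiated
($y = 2^{\hat z}$) so that all three estimators consume the same corrected
signal.

## Bootstrap confidence intervals

`bca_interval()` implements the bias-corrected and accelerated percentile
bootstrap for any scalar estimator over resampled observation units. The
bias correction $z_0$ is the normal quantile of the fraction of bootstrap
estimates below the point estimate — ties count as below with weight 1/2,
which keeps $z_0$ finite for discrete statistics such as count medians — and
the acceleration $a$ is the jackknife skewness. If either correction is not
computable (all resamples on one side), the interval falls back to the plain
percentile interval with a warning; with $z_0 = a = 0$ the two coincide by
construction. Estimator failures on resamples are tolerated up to 20% of
replicates and counted in the result; beyond that the interval is refused as
unstable.

## Two eQTLs per gene: independence versus interaction

When a gene has two distinct eVariants, the independence assumption says the
allelic effects multiply on a haplotype: haplotype $(i_1, i_2)$ expresses
$e_0\,\delta_{v1}^{i_1}\delta_{v2}^{i_2}$, and total expression is again the
sum over the individual's two phased haplotypes.
`fit_independent_two_eqtl()` fits $(\log_2 e_0, s_{v1}, s_{v2}, \alpha)$ by
bounded least squares on log2 expression; `fit_relaxed_two_eqtl()` instead
treats the variant pair as one four-allele variant, giving the
double-alternative haplotype its own effect $s_{11}$ so that
$s_{11} - (s_{10} + s_{01})$ measures the interaction. The relaxed model
nests the independent one; its optimizer is initialized at the independence
solution (with $s_{11} = s_{10} + s_{01}$), which guarantees the nesting
inequality on the fitted residual sums of squares. As in the single-variant
case, the linear parameters are profiled out exactly, and without covariates
the objective collapses onto per-diplotype-class sufficient statistics, so a
fit costs microseconds — which is what makes the bootstrap below practical.

`compare_models()` scores both fits with a plug-in Gaussian likelihood
(maximum-likelihood residual standard deviation) and
$\mathrm{BIC} = -2 \log L + \lambda \log N$, where $\lambda$ counts the
mean-structure parameters only: covariate coefficients plus three
(independent) or plus four (relaxed). The relaxed model is *selected* only
when $\Delta\mathrm{BIC} < 0$ **and** the upper bound of its BCa bootstrap
95% interval — resampling individuals and refitting both models per
replicate — is below zero. Resampling individuals (rather than residuals)
respects the heteroskedastic design; replicates in which a haplotype class
disappears are skipped and counted as failures. Two identical fits differ by
exactly $\log N$, so the criterion is conservative by construction.

```{r twoeqtl}
d <- simulate_two_eqtl_dataset(200, s_v1 = 1, s_v2 = -0.5,
                               interaction_offset = 1,
                               noise_sigma_log10 = 0.05, seed = 2)
cmp <- compare_models(log2(d$expression), d$diplotypes, n_boot = 200, seed = 3)
cmp
```

## The simulator and what the tests do (and do not) show

`simulate_eqtl_dataset()` draws, per eQTL, a reference allele frequency
$f_0 \sim U(0,1)$, genotypes from two Bernoulli trials (Hardy–Weinberg), a
basal haplotype expression $\log_{10} e_0 \sim U(0,4)$, a true effect
$\log_2 \delta \sim U(-5,5)$, and multiplicative noise $\log_{10}
\varepsilon \sim N(0, 0.17)$ — about a 40% coefficient of variation within a
genotype class, the level observed in population RNA-seq. The default
configuration (10,000 eQTLs, 200 individuals) is the benchmark condition;
`benchmark_estimators()` runs all three estimators over it and reports each
method's RMSD against the generating truth. ASE counts are simulated as
binomial draws with success probability $\delta/(1+\delta)$; the two-eQTL
generator draws haplotypes independently per chromosome (no linkage
disequilibrium) with both alternative-allele frequencies 0.5 by default so
every haplotype class is well populated at the cohort sizes used.

The generator reproduces the distributional assumptions of the model, not
real data: no library-size variation, no read-mapping bias, no linkage
disequilibrium between the eVariant and other regulatory variants, no
outliers beyond log-normal noise, and covariates enter only where a test
plants them. Passing tests therefore demonstrate correctness of the
estimators under the model and robustness to its stated noise, not
robustness to artifacts of real pipelines.

Problem sizes in the test suite were chosen to make the statistical
assertions sharp while keeping a full run in the minutes range: the
benchmark at its full 10,000 eQTLs; parameter-recovery at 200 replicates;
model-selection operating characteristics at 500 independence data sets
(noise $\sigma_{\log_{10}} = 0.17$) and 100 interaction data sets; bootstrap
coverage at 500 outer replicates of $B = 1000$. The interaction (power)
data sets use low noise ($\sigma_{\log_{10}} = 0.05$): the selection rule is
deliberately conservative, and at realistic noise a 1-log2-unit interaction
at $n = 200$ sits near the rule's detection boundary (about half the data
sets are selected), so the power check is run where detection should be
essentially certain.

## Benchmark behavior at degenerate allele frequencies

One honest subtlety deserves its own section. With $f_0 \sim U(0,1)$ and 200
individuals, roughly one eQTL in nine has only *two* observed genotype
classes. There the log-scale model is just-identified: M2 and M3 both
reproduce the two class means exactly whenever the implied $\delta$ is
positive, and the two estimators agree. But when noise drives the implied
two-class ratio out of range (e.g. an observed heterozygote mean below half
the reference-homozygote mean), the bounded least-squares fit has no
interior optimum and M2 runs to the $\pm\log_2 100$ bound, while M3 falls
back to its log-linear candidate and returns a moderate estimate. A few
dozen such eQTLs per 10,000 carry squared errors of 10–20 each, enough to
push the *full-set* RMSD of M2 above M3's even though M2 is the more
accurate estimator on every eQTL with all three genotype classes (where it
beats M3 by roughly 5% RMSD, and M1 by far more). The package reports the
benchmark over all estimable eQTLs, keeping each estimator's documented
fallback behavior; users comparing estimators on cohorts with
well-populated genotype classes should expect the M2 ≤ M3 ≤ M1 ordering,
while cohorts rich in rare-homozygote-free eQTLs reward M3's guarded
candidate selection.

## Known limitations

* Estimators are defined for biallelic variants; multiallelic records are
  rejected at the VCF reader (the multi-allele generalization is exposed
  only through the two-eQTL relaxed model's four-haplotype-allele form).
* Joint fitting covers at most two eVariants per gene; predicted effects
  for more variants can be composed by additivity but are not fitted.
* The ASE path assumes upstream site-level quality control (coverage,
  mappability, genotyping error) has already been applied.
* eQTL discovery, latent-factor inference and read counting are out of
  scope; the package consumes their outputs.
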