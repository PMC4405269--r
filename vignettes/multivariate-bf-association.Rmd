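---
title: "Multivariate Bayes factor association analysis of correlated phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate Bayes factor association analysis of correlated phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvbfscan)
```

## The problem

Genome-wide association studies of panels of related quantitative traits —
here the motivating application is cholesterol concentrations in IDL/LDL
lipoprotein subfractions, measured before and during statin treatment —
usually analyze one trait at a time. That throws away two kinds of
information: a variant may affect several traits at once, and the
*pattern* of effects relative to the correlation among traits carries
evidence of its own. `mvbfscan` implements a joint Bayesian analysis in
which, for each SNP with dosage $g$, every way the $d$ phenotypes
$Y_1,\dots,Y_d$ could relate to $g$ is scored and averaged.

## The model

A *partition* $\gamma = (U, D, I)$ assigns each phenotype to one of three
classes:

* $U$ — unassociated: independent of $g$;
* $D$ — directly associated: distribution depends on $g$ even after
  conditioning on the other phenotypes;
* $I$ — indirectly associated: associated with $g$, but conditionally
  independent of it given the phenotypes in $D$ (the association is
  mediated).

Under a multivariate normal model the joint density factorizes as
$P(Y_U)\,P(Y_D \mid Y_U, g)\,P(Y_I \mid Y_U, Y_D)$, with only the middle
term depending on $g$. The Bayes factor of $\gamma$ against the null
$\gamma_0$ (all phenotypes in $U$) therefore reduces to a Bayesian
multivariate regression Bayes factor of $Y_D$ on the centered dosage with
covariates $W = [\mathbf 1, Y_U]$. With the genotype effect row given the
prior $b \mid \Sigma \sim N(0, \sigma_a^2 \Sigma)$ and a scale-invariant
prior on $\Sigma$, it has the closed form

$$
\log \mathrm{BF}_\gamma
 = -\tfrac{|D|}{2}\,\log\!\big(1 + \sigma_a^2\, \tilde g^\top \tilde g\big)
   - \tfrac{\nu}{2}\,\big[\log\det R_1 - \log\det R_0\big],
$$

where $\tilde Y, \tilde g$ are $Y_D$ and $g$ residualized against $W$,
$\nu = n - 1 - |U|$, $R_0 = \tilde Y^\top \tilde Y$, and
$R_1 = R_0 - c\,(\tilde Y^\top\tilde g)(\tilde g^\top \tilde Y)$ with
$c = \sigma_a^2 / (1 + \sigma_a^2 \tilde g^\top \tilde g)$. Phenotypes in
$I$ cancel between numerator and denominator and never enter the
computation. The degrees-of-freedom convention $\nu = n - 1 - |U|$ is the
one under which $\mathrm{BF}_\gamma \to 1$ as $\sigma_a \to 0$, which we
treat as a basic sanity requirement of the prior.

Because no single partition is known in advance, the overall evidence is
the weighted average over all $3^d - 2^d$ alternatives,

$$
\mathrm{BF}_{av} = \sum_{\gamma \neq \gamma_0} w_\gamma\, \mathrm{BF}_\gamma ,
$$

with weights that put uniform prior probability on the number of
associated phenotypes $A = |D| + |I| \in \{1,\dots,d\}$, uniform
probability on $|D| \in \{1,\dots,A\}$ given $A$, and — our completion,
since only the $(A, |D|)$ level is canonically specified — uniform
probability over the $\binom{d}{A}\binom{A}{|D|}$ concrete assignments
within each class. This exchangeable completion makes the weights sum to
exactly 1 and the analysis invariant to phenotype relabeling.

Each $\mathrm{BF}_\gamma$ is first averaged arithmetically over the prior
effect-scale grid $\sigma_a \in \{0.05, 0.1, 0.2, 0.4\}$ (per allele copy,
in residual-SD units; dosages are mean-centered, not variance-standardized,
so these magnitudes are interpretable on the normalized phenotype scale).
By linearity the order of averaging over $\gamma$ and $\sigma_a$ is
interchangeable. Two reference statistics accompany $\mathrm{BF}_{av}$:
$\mathrm{BF}_{uni} = \frac1d \sum_j \mathrm{BF}_j$ (mean of the univariate
Bayes factors, which tracks the minimum univariate p-value) and
$\mathrm{BF}_{all}$ (all phenotypes in $D$; a MANOVA-like joint test).
Per-phenotype posterior probabilities of direct, indirect and no
association are reported conditional on $\gamma \neq \gamma_0$.

```{r one-fit}
set.seed(1)
g <- simulate_genotypes(800, maf = 0.3)
Y <- cbind(a = 0.25 * g + rnorm(800), b = rnorm(800))
summary(mvbf(Y, g))
```

### Numerical strategy

All per-partition statistics are Schur complements of the
$(d+2)\times(d+2)$ cross-product matrix of $[\mathbf 1, Y, g]$, so the
per-SNP cost after an $O(nd^2)$ precomputation does not grow with $n$;
determinants use Cholesky factors and the rank-one update
$\det(R_0 - c\,uu^\top) = \det R_0\,(1 - c\,u^\top R_0^{-1}u)$, and all
averaging is done in log space with log-sum-exp. Monomorphic SNPs are
rejected; missing dosages are mean-imputed with a warning; phenotype
matrices must be complete (the design targets complete-case trial data).
Near-singular cross-product blocks (collinear phenotypes) raise an error
rather than returning unstable numbers. Ties in top-SNP selection break
toward the lower genomic position.

The closed form is verified in the test suite against an independent
numerical oracle that integrates the marginal likelihood in the opposite
order — analytically over $\Sigma$ (an inverse-Wishart integral) given the
effect row $b$, then by Gauss–Legendre quadrature over $b$ after a tangent
substitution — and agrees to far better than the 1% tolerance the tests
assert.

## Phenotype preparation

Trial phenotypes arrive as raw pre-treatment ($P$) and post-treatment
($T$) measurements in up to six strata (three cohorts crossed with two
genotyping stages, in the motivating design). `prepare_phenotypes()`
applies, within each stratum:

1. quantile transformation of $P$ and $T$ to standard normal scores,
   using $\Phi^{-1}(r/(n+1))$ with midranks for ties — this offset avoids
   infinite scores and is symmetric; alternatives (e.g. Blom) differ
   negligibly and one convention is fixed for reproducibility;
2. $A = (T+P)/2$ and $D = T-P$ — $A$ powers the scan for associations
   present in both visits, $D$ the scan for treatment response
   (a variant whose *standardized* effect differs between visits);
3. per-stratum multiple linear regression of $A$ and $D$ on age,
   log(BMI), sex and smoking status, keeping residuals;
4. a second quantile transformation of the residuals, so each final
   column is an exact permutation of the normal-score set within each
   stratum.

Consequences worth knowing: the pipeline is invariant to any strictly
increasing transformation of the raw inputs, strata are processed
completely independently, and each phenotype is transformed separately
(stage 4 does not pool phenotypes). Missing covariates are an error, not
imputed. No population-structure correction is applied within strata.

## Outlier QC

The engine assumes multivariate normality of residuals. Individuals who
break joint normality despite marginal normality are screened by the
squared Mahalanobis distance $m_i^2 = (y_i-\hat\mu)^\top S^{-1}
(y_i-\hat\mu)$ with the plug-in sample mean and covariance — deliberately
not a robust estimator, matching the definition of the screen — which is
$\chi^2_d$ under the model; individuals with upper-tail $p < 0.01$
(strict) are flagged in a single pass, with no iterative re-estimation.
The screen is run on whichever analysis matrix ($\tilde A$ or $\tilde D$)
is being scanned.

## Two-stage scanning and secondary signals

Enumerating $3^d - 2^d$ partitions per SNP is infeasible genome-wide at
$d = 12$, so the scan is two-stage: `filter_scan()` computes only
$\mathrm{BF}_{uni}$ and $\mathrm{BF}_{all}$ (both vectorized across SNPs),
and SNPs with $\log_{10}$ of either exceeding 1.3 (strict) proceed to
`full_scan()`. The two-stage result is identical to a full scan restricted
to the candidates. As a reporting convention $\log_{10}\mathrm{BF}_{av}
\approx 5\text{–}6$ corresponds roughly to conventional genome-wide
significance; no Bayes-factor-to-p-value conversion is attempted.

`conditional_scan()` looks for independent secondary signals at a locus:
each phenotype is replaced by its residuals from a simple regression on
the top SNP's dosage and the region (default ±150 kb, 1-based inclusive
coordinates) is re-scanned. Re-testing the top SNP on its own residuals
gives $\log_{10}\mathrm{BF}_{av} \approx 0$ by construction.

`decompose_gain()` splits the evidence gain of the multivariate
subfraction analysis over a univariate analysis of a reference phenotype
(total LDL-C in the application) into a measurement part
($\log_{10}\mathrm{BF}_{uni} - \log_{10}\mathrm{BF}_{ref}$) and a
multivariate part ($\log_{10}\mathrm{BF}_{av} -
\log_{10}\mathrm{BF}_{uni}$); the two parts sum to the total exactly.
The gain of the joint analysis is largest when effects are discordant
with the phenotype correlation — e.g. opposite-sign effects on positively
correlated subfractions that cancel in total LDL-C.

## Effect summaries

`effect_profile()` (simple regression slope ± SE per phenotype),
`genotype_class_profile()` (class means with classes at proportion ≤ 0.01
omitted; dosages are rounded to classes only for display, regressions use
unrounded dosages), `sequential_conditional_effects()` (two-SNP
replication procedure), `mediation_adjust()` (percent change of the SNP
effect after adding a mediator such as HDL-C as a covariate; the sign
convention makes attenuation toward zero negative),
`treatment_change_summary()` (per-individual absolute and fractional
statin change, fractional change computed per individual then averaged,
as the per-individual SD bands of such displays require), and
`treated_untreated_contrast()`. PVE uses the standard biallelic additive
formula $2\,\mathrm{maf}(1-\mathrm{maf})\beta^2/\mathrm{var}(y)$.

## The synthetic-trial generator

Individual-level data of the motivating study are not public, so the
package ships a generator ([truth_spec()], [simulate_trial()]) that
emulates the study design and carries its ground truth alongside the
data. The default full-design preset (`truth_spec_table1()`) encodes:

* 3 cohorts (581 / 797 / 490 individuals; 1868 total) × 2 genotyping
  stages = 6 strata. The published design does not state per-stage sizes,
  so stages split each cohort 60/40 — a design choice, fixed once.
* 12 phenotypes (total LDL-C, LDL peak diameter, 10 IDL/LDL subfraction
  concentrations) with per-cohort raw-scale pre- and post-treatment means
  and SDs matching the published cohort summaries (e.g. CAP LDL-C
  132 ± 33.2 mg/dL untreated, 76.7 ± 23.7 treated, so the configured
  statin shift is −55.3 mg/dL); cohort-level age, BMI, sex and smoking
  distributions likewise.
* A residual correlation among the 12 phenotypes built from a two-factor
  model (overall concentration + particle size), giving positive
  correlations among adjacent subfractions that decay with distance and
  negative correlation between the largest and smallest subfractions.
  The true study covariance is published only as a figure, so this is a
  qualitative, explicitly configurable emulation.

Genetic effects follow the partition structure exactly: $U$ phenotypes
are residual noise, $D$ phenotypes receive $(g - 2\,\mathrm{maf})\beta$,
and $I$ phenotypes are loadings on the $D$ phenotypes plus *independent*
residual noise. The residuals of $I$ phenotypes are drawn independent of
the $U/D$ residuals deliberately: if they shared residual correlation
with $D$, the generated $I$ phenotypes would not be conditionally
independent of $g$ given $Y_D$, breaking the very structure the class is
meant to represent. Genetic and covariate contributions are mean-centered
so the configured stratum means are exact targets. Pre/post residuals
share a between-visit correlation (default 0.7, a realistic value for
repeated lipid measures over weeks; the published summaries do not
constrain it). Treatment response enters as a genotype × treatment
interaction `response_beta` added to the post-treatment standardized
effect. Optional uniform dosage noise mimics imputed dosages.
`inject_outliers()` displaces individuals along directions uniform on the
covariance-whitened sphere, so the displacement magnitude maps directly
onto the expected Mahalanobis distance.

What the generator does *not* emulate: linkage disequilibrium between
SNPs (`simulate_genotype_matrix()` draws independent SNPs), population
structure, genotyping-chip artifacts, assay-specific measurement error,
and non-normal phenotype tails. Passing tests on these data therefore
demonstrate the statistical machinery under its own model assumptions —
calibration, recovery, invariances — not robustness to every failure mode
of real cohort data.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise: oracle agreement at
$n = 20$, $d \le 3$, $|D| \le 2$ over the full $\sigma_a$ grid; null
calibration with 500 SNPs at $n = 1000$, $d = 4$; partition recovery with
50 replicates at $n = 2000$, $d = 4$ and a 2%-of-variance direct effect;
secondary-signal retention in two-causal-SNP regions; the sign-flipping
six-subfraction gain scenario at $n = 2000$; and one full 12-phenotype,
1868-individual trial analysis. These sizes were chosen to make the
Monte-Carlo margins decisive for each property while keeping a complete
run fast on a single CPU.

## Known limitations

* Full partition enumeration is exponential in $d$ (about 55 s per SNP at
  $d = 12$ on one core); the two-stage filter is the intended genome-wide
  mode, and $d \le 14$ is enforced.
* For a phenotype truly unrelated to the SNP and nearly uncorrelated with
  the associated phenotypes, the $U$ and $I$ placements fit the data
  equally well asymptotically, so its posterior probability of
  association converges to its conditional prior mass (≈ 0.5 under the
  default weights when two other phenotypes carry a strong signal) rather
  than to 0. Posteriors for such phenotypes should be read as "not
  distinguishable from inert", not as evidence of association; the
  decisive quantity for discovery is $\mathrm{BF}_{av}$.
* No MCMC or variational approximation, no shrinkage estimation of
  $\Sigma$, no multi-SNP joint models, no LD-aware clumping or
  meta-analysis.
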