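---
title: "Association scans with related individuals and repeated measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association scans with related individuals and repeated measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmgwas)
```

## The problem

Long-term field studies of wild populations (flycatchers, tits, Soay sheep,
...) capture and phenotype the same marked individuals year after year. A
genome-wide association study (GWAS) on such data faces two sources of
correlation that ordinary per-SNP regression ignores: individuals are
related (family structure inflates test statistics) and the same individual
contributes several records (within-individual correlation inflates them
further). Collapsing records to per-individual averages sidesteps the second
problem but throws away information and, more importantly, makes it
impossible to model time-varying covariates such as year or age — and yearly
environmental variation is often a large slice of the phenotypic variance in
the field.

## The model

`rmgwas` fits, for each SNP,

$$y = X\beta + x_{snp}\beta_{snp} + Zg + Zp + \varepsilon$$

where $y$ is the vector of $N$ observation-level records on $n$ individuals,
$Z$ the 0/1 incidence matrix mapping records to individuals,
$g \sim N(0, \sigma_g^2 G)$ the polygenic effect with $G$ the VanRaden
genomic relationship matrix, $p \sim N(0, \sigma_p^2 I_n)$ the permanent-
environment effect capturing all non-genetic individual-level covariance,
and $\varepsilon \sim N(0, \sigma_e^2 I_N)$. Marginally,
$V = ZGZ'\sigma_g^2 + ZZ'\sigma_p^2 + I_N\sigma_e^2$.

Fitting this mixed model afresh at every SNP would be prohibitive, so the
scan is two-stage:

1. **Null fit.** The model *without* any SNP effect is fitted by REML
   (`fitNull()`), giving variance-component estimates and the fitted
   covariance $V_0$.
2. **Whitened per-SNP least squares.** Each SNP is fitted by generalized
   least squares with $V_0$ held fixed (`rglsScan()`). Writing
   $V_0 = \Gamma\Lambda\Gamma'$, premultiplying the model by a whitening
   operator turns it into ordinary least squares with independent
   homoscedastic residuals; the effect estimate and a Wald statistic (RSS
   with denominator $N - \mathrm{rank}$, referred to the standard normal)
   follow at the cost of a few matrix products per SNP. With $V_0 = I$ the
   procedure reduces to plain per-SNP regression.

Because $V_0$ is estimated once, part of a very large SNP effect is
absorbed by the polygenic component (the polygenic variance is overestimated
when strong QTLs segregate), but the per-SNP tests remain calibrated — the
package's replicate harness reproduces this behavior.

### Numerical design

* The REML objective is evaluated through the low-rank identity
  $V = ZAZ' + \sigma_e^2 I$, $A = \sigma_g^2 G + \sigma_p^2 I$: with
  $B = ZD^{-1/2}$ ($D = Z'Z$, diagonal) and $M = D^{1/2}AD^{1/2}$, every
  evaluation needs only $n \times n$ algebra, and
  $\log|V| = (N-n)\log\sigma_e^2 + \log|M + \sigma_e^2 I|$. For balanced
  designs ($D = rI$) $M$ diagonalizes in the eigenbasis of $G$, which is
  memoized on the `RelationshipMatrix`, so an evaluation costs $O(np^2)$.
* Optimization is L-BFGS-B on log-variances (positivity by construction),
  started at one third of the residual variance of the fixed-effects fit,
  with a lower bound of $10^{-8}\,\mathrm{var}(y)$; components ending at
  the bound are reported as 0 with a boundary flag.
* The whitening operator is the *symmetric* inverse square root
  $V_0^{-1/2} = \Gamma\Lambda^{-1/2}\Gamma'$ rather than
  $\Lambda^{-1/2}\Gamma'$. The two differ by an orthogonal factor, so
  rotated-OLS estimates, residual sums of squares and Wald tests are
  identical, and the symmetric root composes directly with the low-rank
  factorization: the $N$ eigenvalues of $V_0$ are the $n$ values
  $\mathrm{eig}(M) + \sigma_e^2$ plus $\sigma_e^2$ with multiplicity
  $N - n$, and no dense $N \times N$ decomposition is ever formed.
* Eigenvalues of the fitted covariance are floored at $10^{-8}$ of the
  largest before inversion; relationship matrices are clipped to
  positive-semidefinite if tiny negative eigenvalues arise from missing-data
  imputation.
* Per-SNP dosages are mean-imputed ($2\hat p$); SNPs with zero dosage
  variance are flagged and excluded from the inflation factor.
* The genomic-control factor is the median of the observed 1-df chi-square
  quantiles over its null median (0.4549); a regression-through-origin
  variant is available (`inflationLambda(..., method = "regression")`).

## Worked example

```{r example, eval = FALSE}
gm0 <- simulateGenotypes(nFamilies = 150, sibsPerFamily = 2,
                         nUnrelated = 549, nSnps = 10000, seed = 1)
qc <- qcFilter(gm0)           # call rate >= 0.95, MAF >= 0.01, HWE p > 0.001
gm <- qc$genotypes
grm <- computeGRM(gm)

sim <- simulateGaussian(gm, qtlIndices = 5000, qtlEffects = 1,
                        components = c(1, 1, 1),
                        design = designSpec("balanced", 4),
                        seed = 1, grm = grm)
fit <- fitNull(sim$pheno, ~ 1, grm)
fit
scan <- rglsScan(gm, fit)
scan
significantSnps(scan)
```

## What the simulator emulates — and what it does not

The generator mirrors the simulation design of the methodological study the
package implements: a genotyped wild population of 849 individuals in which
a subset are close relatives (here, 150 full-sib pairs produced by Mendelian
transmission from unobserved founder parents, plus 549 unrelated
individuals; sib pairs show genomic relationships near 0.5), 10,000
bi-allelic SNPs with allele frequencies uniform on (0.01, 0.5), variance
components $(\sigma_g^2, \sigma_p^2, \sigma_e^2) = (1, 1, 1)$, and either a
balanced design (a fixed number of records per individual) or an unbalanced
one with Poisson(2) record counts — the one standard count law whose mean
and variance are both 2. Individuals drawing zero records are absent from
that replicate; this slightly raises the conditional mean count, which we
document rather than correct since only the marginal moments are specified.
Year effects are i.i.d. Gaussian draws shared by all records of a year
(default 10 study years, uniform assignment, years not repeated within an
individual when avoidable); a share $s$ of total variance is induced by
setting $\sigma_{year}^2 = 3s/(1-s)$ against the non-year variance of 3.
They are *simulated* as random but *fitted* as fixed effects, as is standard
in field analyses.

Real data differ in ways the simulator does not capture: linkage
disequilibrium between markers (our SNPs are independent), a realistic
pedigree depth beyond full sibs, ascertained allele-frequency spectra,
genotyping error, and non-Gaussian trait distributions. Passing simulation
checks therefore demonstrates the statistical machinery, not robustness to
every field complication.

Panel density matters for calibration: when the tested SNP is a visible
fraction of the relationship matrix (a few hundred SNPs), its own polygenic
term absorbs part of the association and the test becomes conservative.
At the 10,000-SNP scale used throughout, this effect is negligible.

## Binary traits

Binary phenotypes are simulated by thresholding a Gaussian liability at
$\tau$, anchored so that $\tau = 0$ gives an equal split of zeros and ones
among common-allele homozygotes. Scanning a 0/1 trait with the Gaussian
machinery estimates, in expectation, the population least-squares slope of
penetrance on dosage under Hardy–Weinberg weights
(`expectedObservedSlope()`); a liability-scale polygenic variance
$\sigma_g^2$ appears on the observed scale as
$\varphi(\tau/\sigma_u)^2\sigma_g^2/\sigma_u^2$
(`expectedObservedGeneticVariance()`), which at the defaults
($\sigma_g^2 = 1$, $\sigma_u^2 = 3$, $\tau = 0$) equals 0.053. The non-QTL
liability variance ($\sigma_u^2 = 3$ at the defaults) is the correct
denominator because the threshold is anchored at the common-homozygote mean;
this choice is validated in the test suite by reproducing the expected
observed-scale estimates across a range of thresholds from the corresponding
population proportions of ones, each solved back to an effective allele
frequency with `solveAlleleFreq()`. For traits with extreme proportions
(below 5% or above 95% ones) the Gaussian approximation degrades and a
binomial-response model should be used to confirm top hits; that model is
outside this package's scope.

## The individual-averages baseline

`scanAverages()` implements the comparison method: per-individual mean
phenotypes analysed with a two-component polygenic model
($V = G\sigma_g^2 + I\sigma_e^2$; with one record per individual a
permanent-environment component is not separable) and the identical
whitened scan. Individuals are deliberately weighted equally regardless of
their record counts, mirroring the naive practice the repeated-measures
model improves upon. `compareMethods()` and `yearEffectSweep()` quantify
the power gain as the percent increase in mean $-\log_{10}p$ at the
simulated QTL, using the ratio of replicate means (the alternative — mean of
per-replicate ratios — is noisier and is not reported). Sweeps over the
year-variance share use common random numbers: replicate $r$ reuses its
genetic, permanent-environment and residual draws across shares, so the
trend in the share is not masked by between-replicate noise. On synthetic
genotypes the gain is a few percent without year effects and rises steeply
with the year-variance share (order 30–40% at a 57% share, with the
between-method correlation of $-\log_{10}p$ falling well below 1); the
magnitudes depend on the genotype panel and the number of study years, so
only the direction and monotone trend are asserted in the tests.

## Problem sizes and defaults

Simulation-based checks run at 849 individuals × 4 records × 10,000 SNPs
with 50–100 replicates (null calibration, effect recovery, type-I error,
binary variance components), and at 300 individuals × Poisson(2) records ×
400 SNPs with 20 replicates per year-share for the baseline comparison.
QTLs are placed on SNPs with MAF ≥ 0.05 where an effect of 1.0 is simulated.
QC defaults (call rate ≥ 0.95, MAF ≥ 0.01, HWE p > 0.001) follow standard
array practice.

## Known limitations

* Variance components are REML point estimates; their uncertainty is not
  propagated into the scan (the two-stage approximation shared by all
  GRAMMAR-family methods).
* Only the three-kernel covariance (polygenic, permanent environment,
  residual) is exposed, although the engine is written against a general
  individual-level kernel $A$.
* The scan tests SNPs one at a time with no built-in multiple-testing
  correction beyond the `significantSnps()` helper.
* X-chromosome dosage models, dominance and epistasis are out of scope.
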