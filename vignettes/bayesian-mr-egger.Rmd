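---
title: "Bayesian MR-Egger: model, simulator and design notes"
author: "pleioMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian MR-Egger: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioMR)
```

## The estimation problem

Two-sample Mendelian randomization estimates the causal effect
$\theta$ of an exposure $X$ on an outcome $Y$ from per-SNP marginal
association statistics: $\hat\alpha_j \pm \hat\sigma_{\alpha j}$ with
the exposure (sample 1) and $\hat\beta_j \pm \hat\sigma_{\beta j}$
with the outcome (sample 2), $j = 1, \dots, J$ independent instruments.
Under valid instruments $\beta_j = \theta\,\alpha_j$; a direct
(pleiotropic) SNP effect $\varphi_j$ on the outcome adds an intercept:
$\beta_j = \varphi_j + \theta\,\alpha_j$.

All regression-based estimators in this package are generalized least
squares with outcome weight matrix
$\Omega_{jk} = \hat\sigma_{\beta j}\hat\sigma_{\beta k}\rho_{jk}$
($\rho$ = identity for independent SNPs; a user-supplied correlation
matrix plugs into the same expressions):

* **IVW** — design $A = [\hat\alpha]$, no intercept:
  $\hat\theta_{IVW} = (A^{\mathsf T}\Omega^{-1}A)^{-1}
  A^{\mathsf T}\Omega^{-1}B$.
* **MR-Egger** — design $A = [1\;\hat\alpha]$; the intercept estimates
  the average directional pleiotropy, and the slope is consistent
  under the InSIDE assumption (pleiotropic effects independent of
  instrument strengths across SNPs).
* **BMRE** — the same Egger likelihood with an independent normal
  prior $(\varphi, \theta) \sim N(\mu_0, \Sigma_0)$,
  $\Sigma_0 = \mathrm{diag}(\sigma^2_{\mu\varphi},
  \sigma^2_{\mu\theta})$; the conjugate posterior is
  $N(\mu_N, \Sigma_N)$ with
  $\mu_N = (A^{\mathsf T}\Omega^{-1}A + \lambda_0)^{-1}
  (\lambda_0\mu_0 + A^{\mathsf T}\Omega^{-1}B)$,
  $\Sigma_N = \hat\sigma^2_\varepsilon
  (A^{\mathsf T}\Omega^{-1}A + \lambda_0)^{-1}$,
  $\lambda_0 = \Sigma_0^{-1}$. No sampler is needed; the posterior is
  exact.
* **Weighted median** — the 50th weighted percentile of the ratios
  $\hat\beta_j/\hat\alpha_j$ with weights
  $w_j = \hat\alpha_j^2/\hat\sigma^2_{\beta j}$; consistent while at
  least half the total weight comes from valid instruments.

A tight zero-mean prior on the intercept
($\sigma^2_{\mu\varphi} \to 0$) collapses BMRE onto IVW; vague priors
on both coordinates recover MR-Egger. Weakly informative intercept
priors interpolate: they buy back much of the power MR-Egger loses
while still allowing a plausible amount of directional pleiotropy.
Both limits are verified numerically in the test suite (tolerance
$10^{-3}$ at variances $10^{-12}$ and $10^{6}$).

### Dispersion and inference

All estimators share the multiplicative random-effects rule. With
precision-weighted residuals
$\hat\varepsilon = \mathrm{diag}(\Omega^{-1})^{1/2}(B - A\hat c)$,

$$\hat\sigma^2_\varepsilon = \frac{1}{J-k}\sum_j \hat\varepsilon_j^2,$$

and the scale entering standard errors is
$\max(\hat\sigma^2_\varepsilon, 1)$: overdispersion (heterogeneity
beyond sampling noise) widens intervals, underdispersion never narrows
them. $k$ is the number of regression parameters (1 for IVW, 2 for
MRE/BMRE). For BMRE the residuals are evaluated at the posterior mean
$\mu_N$ with $k = 2$ — the only fitted coefficient the conjugate
scheme produces.

Rejection, for every estimator, means the symmetric 95% (credible)
interval $\pm z_{0.975} \times$ scale excludes zero. The normal
quantile is used throughout; no degrees-of-freedom correction is
applied. One consequence, visible in the simulations below, is that
tests are mildly conservative at the null (rates near 0.041 rather
than 0.050): the clamp can only widen intervals, never narrow them.

### Orientation

Egger regression is not invariant to the arbitrary choice of effect
allele, so `orientInstruments()` recodes every SNP with
$\hat\alpha_j < 0$ by flipping the sign of both $\hat\alpha_j$ and
$\hat\beta_j$. All fitting functions orient internally; a joint sign
flip of any subset of SNPs therefore leaves every estimate unchanged
(a property test covers IVW, MRE, BMRE and WM).

### Weighted-median uncertainty

No closed-form variance is used for the weighted median. The scale is
a parametric bootstrap: `nBoot` (default 1000) resamples
$\hat\alpha_j^\ast \sim N(\hat\alpha_j, \hat\sigma^2_{\alpha j})$,
$\hat\beta_j^\ast \sim N(\hat\beta_j, \hat\sigma^2_{\beta j})$,
re-estimating the weighted median on each; the SD of the resampled
estimates is the reported scale. A SNP with $\hat\sigma_{\alpha j} = 0$
keeps its exposure effect fixed. The bootstrap is seeded explicitly.
Sorted ratios are placed at cumulative percentiles $(s_j - w_j/2)/S$
($s_j$ = cumulative weight, $S$ = total) and the median is linearly
interpolated between adjacent ratios; with $J \ge 2$ positive weights
the 0.5 point always falls inside the percentile range, and a single
ratio sits exactly at the median.

## The simulator

`simulateCohort()` generates individual-level data per the structural
equations

$$U_i = \sum_j \omega_{1j} G_{ij} + \varepsilon_u,\qquad
  X_i = \sum_j \alpha_j G_{ij} + \omega_2 U_i + \varepsilon_x,\qquad
  Y_i = \sum_j \varphi_j G_{ij} + \theta X_i + \omega_3 U_i +
        \varepsilon_y,$$

with genotypes $G_{ij} \in \{0,1,2\}$ drawn under Hardy–Weinberg
equilibrium at MAF 0.30 (equivalently Binomial(2, 0.30)), instrument
strengths $\alpha_j \sim U(0.5, 4)$, and confounder effects
$\omega_2 = \omega_3 = 1$. `makeTwoSample()` draws the per-SNP
parameters once, simulates two independent cohorts of $n = 1000$
sharing them, and reduces each to summary statistics by per-SNP simple
linear regressions (with intercept — the structural equations set the
intercept to zero, but marginal regressions on a genotype with mean
$2\times 0.3 = 0.6$ require one): exposure on genotype in cohort 1,
outcome on genotype in cohort 2.

**Noise parameterization.** The error terms are $N(0, 2)$ with 2 read
as the *standard deviation* (`noiseParam = "sd"`, the default; the
variance reading remains available as `noiseParam = "variance"`). The
"2 = SD" reading is the one under which the simulator reproduces the
study's reported operating characteristics — under scenario II at
$\theta = 0$ it yields IVW/WM type-1 errors of ≈0.73/0.44, matching
the reported values, whereas the variance reading yields ≈0.93/0.71 —
and it is what `rnorm(n, 0, 2)` produces in R.

**Scenario presets** (`scenarioPreset()`): I — no pleiotropy; II — all
SNPs pleiotropic, $\varphi_j \sim U(0, 0.2)$; III — as II with InSIDE
violated via $\omega_{1j} \sim U(0, 0.5)$; IV — each SNP pleiotropic
independently with probability $q \in \{0.1, \dots, 0.4\}$ and
$\varphi_j \sim U(0, 0.5)$ (mean pleiotropy $0.25q$, spanning
0.025–0.100; the narrower $U(0, 0.2)$ range is available as a
`phiRange` override but does not reproduce those averages); V — as IV
with $q = 0.4$ plus InSIDE violation $\omega_{1j} \sim U(L, B)$,
$B \in \{0.1, 0.3, 0.6, 1.0\}$, $L \in \{0, -B\}$. In scenarios IV–V
one Bernoulli($q$) indicator per SNP switches both $\varphi_j$ and
$\omega_{1j}$, so the InSIDE violation attaches to the pleiotropic
SNPs. Pleiotropic SNP counts are therefore binomial around $qJ$, not
fixed at $\lfloor qJ \rfloor$.

What the generator deliberately does *not* emulate: linkage
disequilibrium between instruments (SNPs are independent; correlated
instruments enter only through a user-supplied correlation matrix on
the summary side), binary outcomes (the generating model is
linear-Gaussian, while empirical MR of disease outcomes works on the
log-odds scale), weak-instrument selection effects, and sample overlap
between the two cohorts. Passing simulation tests therefore speak to
estimator behaviour under the stated linear two-sample conditions, not
to robustness against those real-data features.

## The study harness

`runStudy()` fixes a master seed, spawns one child seed per replicate
(logged in the output so any replicate is reproducible in isolation),
and fits every requested estimator on the *same* generated dataset per
replicate — a shared-data design that removes between-method
Monte-Carlo noise from comparisons without affecting marginal rates.
`computeMetrics()` reduces the replicate table to bias
$\bar\theta - \theta$, empirical SE (denominator $n-1$), RMSE
$\sqrt{\mathrm{bias}^2 + \mathrm{ESE}^2}$ and rejection rates;
`mcBounds()` gives the binomial bounds within which an empirical rate
is consistent with its nominal value (0.044–0.056 at 5000 replicates,
nominal 0.05).

Problem sizes used by the shipped checks: the acceptance script and
the scenario II blocks run 2000 replicates (empirical rates then carry
a Monte-Carlo SE of about 0.01 at rates near 0.5, so comparisons use
±0.03 tolerances); the nominal-level calibration block runs 20000
replicates because the quantity of interest (a true rate near 0.041)
sits close to the acceptance band edge at 0.039, and 2000-replicate
noise (SE ≈ 0.0045) would dominate the check. The hyperparameter grid
of the full study is available as `priorGrid()`:
$\mu_\varphi \in \{0, 0.05, 0.10, 0.15\}$,
$\sigma^2_{\mu\varphi} \in \{10, 10^{-2}, 10^{-2.4}, 10^{-2.7},
10^{-3}\}$, slope prior $N(0, 10)$.

```{r study, eval = FALSE}
tab <- runStudy(scenarioPreset("II", theta = 0),
                estimators = c("IVW", "MRE", "BMRE", "WM"),
                priors = priorGrid(), nReps = 5000, masterSeed = 1)
computeMetrics(tab, thetaTrue = 0)
```

## Eliciting priors from observed pleiotropy

When associations of the instruments with secondary phenotypes are
available, `pleiotropyProfile()` summarizes them: the fraction of
effects within a band, a balance summary (mean effect, share
positive), and the entries reaching genome-wide significance
($p < 5\times 10^{-8}$; the conventional threshold, adopted here as
the default since no other value is forced by the method). SNPs with
clear signals can be excluded, or — the BMRE route — kept while the
observed spread calibrates the intercept prior:
`elicitPriorVariance(band, coverage)` returns
$(\mathrm{band}/z_{(1+\mathrm{coverage})/2})^2$, e.g. a ±0.05 band at
95% gives $6.508\times 10^{-4}$. `runEmpiricalAnalysis()` then fits
IVW, MRE, WM and one BMRE per prior, optionally exponentiating
estimates and interval bounds to odds ratios — estimation always
happens on the log-odds scale, and only the report is transformed, the
transform being monotone.

## Numerical and design notes

* Closed-form solves use the normal equations with an `rcond` guard;
  the test suite cross-checks IVW/MRE against a Cholesky-whitened
  `lm()` oracle and BMRE against augmented-data least squares to 10
  significant digits, including non-identity correlation matrices.
* Degenerate inputs error loudly: $J \le k$ ("insufficient
  instruments"), identical $\hat\alpha_j$ (collinear with the Egger
  intercept), any $\hat\alpha_j = 0$ for the weighted median, a
  non-positive-definite weight matrix. A zero $\hat\alpha_j$ only
  warns for the regression estimators, where it is well defined.
* Prior variances must be strictly positive; the IVW limit is reached
  numerically (e.g. $10^{-12}$), not by a zero-variance fit.
* A genotype column with no variation (possible only at tiny $n$ or
  extreme MAF) triggers one cohort re-draw, then an error.
* Simulation reproducibility is bit-exact for a given seed; the
  weighted-median bootstrap scale is order-dependent only through its
  Monte-Carlo noise (the point estimate is exactly permutation
  invariant).
* The intercept-rejection decision for BMRE uses central
  credible-interval exclusion of zero, the same rule as the
  frequentist estimators, keeping rejection rates comparable across
  methods; a posterior tail probability would be an equally defensible
  Bayesian choice and differs negligibly for these symmetric
  posteriors.

## Limitations

BMRE inherits MR-Egger's dependence on InSIDE: when instrument
strengths correlate with direct effects, every estimator here is
biased, and informative intercept priors pull BMRE's bias and
rejection rates towards IVW's. The conjugate scheme conditions on
$\hat\sigma^2_\varepsilon$ rather than integrating over it (no
inverse-gamma layer), mirroring the plug-in dispersion of the
frequentist fits. Exposure-side uncertainty
$\hat\sigma_{\alpha j}$ is carried in the data container and used by
the weighted-median bootstrap, but — as in standard IVW/Egger
regression — not propagated through the regression estimators (no
measurement-error or SIMEX correction is attempted).
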