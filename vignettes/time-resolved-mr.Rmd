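---
title: "Time-resolved Mendelian randomization: model, estimator and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved Mendelian randomization: model, estimator and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronomr)
```

## The estimand

Mendelian randomization treats a genetic instrument $G$, fixed at
conception, as a proxy for a modifiable exposure $x$ (think of a polygenic
score for body-mass index).  Because the genotype acts over the whole life
course, the effect it transmits to a disease outcome is *cumulative*: what
an additive-hazards survival model estimates for $G$ at age $T$ is

$$H(T) = \int_0^T \gamma(t)\,\beta_G(t)\,dt,$$

where $\beta_G(t)$ is the instrument effect on the exposure at age $t$ and
$\gamma(t)$ is the *momentaneous* effect of the exposure — the change in the
hazard rate per additional year of one-SD-higher exposure at age $t$.  The
scientific quantity of interest is the *life-course (cumulative) effect*

$$\Gamma(T) = \int_0^T \gamma(t)\,dt,$$

the hazard-rate difference at age $T$ between two exposure trajectories one
SD apart since conception.  When $\beta_G$ varies with age — which is well
documented for BMI-associated variants — the usual Wald ratio
$H(T)/\beta_G(T)$ is *not* $\Gamma(T)$: the accumulated outcome effect at
$T$ depends on $\beta_G(t)$ at all earlier $t$.  Dividing by a time-averaged
$\bar\beta_G$ fails the same way.  The time-resolved estimator instead
divides the *time gradient* of $H$, for which
$\dot H(t) = \gamma(t)\beta_G(t)$ holds pointwise:

$$\hat\gamma(t_{k-1/2}) =
  \frac{\hat H(t_k) - \hat H(t_{k-1})}{\beta_G(t_{k-1/2})},\qquad
  \hat\Gamma(t_k) = \sum_{i\le k}\hat\gamma(t_{i-1/2}).$$

Key assumptions: the instrument is valid (relevance at *every* age in
follow-up, no horizontal pleiotropy, no confounding of the
instrument–outcome relation); effects are additive on the hazard scale; and
a prompt change in exposure produces an instant, irreversible change in the
latent outcome process (short disease latency).  Under the last assumption
$\dot\Gamma$ is interpretable as $\gamma$; with long latencies the estimate
is a time-blurred version of it.

## The estimation pipeline

1. **Exposure preparation** (`ztransform_by_stratum`): the raw exposure is
   z-scored within sex-by-age strata (boundary strata pooled at $\le 40$ and
   $\ge 70$ years), putting the age-varying instrument effect on a common SD
   scale.  Synthetic cohorts are generated on that scale directly, so the
   pipeline's `standardize` flag is off by default.
2. **Instrument construction** (`crossfit_pgs`, `steiger_filter`): polygenic
   scores are cross-fitted — each half-sample is scored with weights
   estimated in the other half, standardized per half, then merged — so no
   individual is scored with weights overfitted to its own data.  Steiger
   filtering removes variants that do not explain significantly more
   variance in the exposure than in the outcome (one-sided test on two
   dependent overlapping correlations, Fisher-z transformed,
   Benjamini–Hochberg at FDR 0.05), guarding against reverse causation.
3. **Instrument effect on exposure** (`fit_beta_quartic`): least squares of
   the standardized exposure on $G$, $G\cdot t$ and $G\cdot t^4$ (raw years,
   main age terms included, covariates additive), restricted to individuals
   event-free at assessment.  The quartic shape follows the observed
   adult-age curvature with linear behaviour toward young ages; a linear
   model (`fit_beta_linear`) is the fallback when the quartic extrapolation
   crosses zero.  Confidence bands use the delta-method variance
   $g(t)^\top\Sigma\,g(t)$, $g(t) = (1, t, t^4)$.
4. **Instrument effect on outcome** (`fit_aalen`, `yearly_increments`):
   Aalen's additive hazards model with all covariate effects time-varying,
   estimated from scratch as risk-set least squares at each event time, with
   the per-event variance contribution $b b^\top$.  Event ages recorded in
   whole years are jittered uniformly within the year to break ties; the
   yearly effect $\hat H(t_k)$ is the difference of the cumulative
   coefficient between the last events of consecutive years.  Follow-up is
   administratively censored at 76 years by default (boundary effects and
   low counts above that age); the synthetic validation studies, whose
   generator is free of those artifacts, analyze to 80.
5. **Wald ratios and integration** (`effect_series`): midpoint-rule
   $\hat\Gamma$ (uncorrelated increments; used by all downstream stages) and
   trapezoid-rule $\hat\Gamma$ (smaller variance, correlated neighbours;
   used for presentation), with the variance approximations
   $\sigma_k^2/\beta_G^2(t_k)$ (midpoint) and the trapezoid forms including
   their $k = 1, 2$ special cases.  Two deliberately naive comparators are
   computed alongside: $\hat H(T)/\bar\beta_G$ and $\hat H(T)/\beta_G(T)$.
6. **Trends** (`local_slope`, `hp_filter`, `bootstrap_trend_bands`): the
   smoothed momentaneous effect $\bar\gamma(T)$ is the slope of a weighted
   local-linear fit to $\hat\Gamma$ with a raised-cosine kernel
   ($\tfrac12\cos(\pi u/b)+\tfrac12$, FDHM $b = 10$ years — structures
   closer than $b$ are not resolved); the trend of $\hat\Gamma$ is a
   Hodrick–Prescott filter with $\lambda = 50$.  Bands come from a
   parametric bootstrap (default 10,000 samples): independent
   $N(0, \sigma_k^2/\beta_G^2(t_k))$ noise is added to $\hat\Gamma$, the
   trend is refitted, and the 2.5%/97.5% quantiles are taken per age.  Only
   the series noise is resampled; the instrument and Aalen fits are held
   fixed.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_follow_age` | 76 yr | administrative censoring of the analysis |
| `beta_model` | quartic | shape of $\beta_G(t)$; linear as fallback |
| weak-instrument `floor` | 0.01 SD | smallest admissible $|\beta_G(t)|$ before the Wald ratio is refused |
| `b` | 10 yr | kernel FDHM = temporal resolution of $\bar\gamma$ |
| `lambda` | 50 | HP stiffness for the $\Gamma$ trend |
| `n_boot` | 10,000 | parametric bootstrap samples |
| `alpha` | 0.05 | confidence level (multiplier 1.96) |

## The synthetic validation cohort

`simulate_cohort` generates data under the model the estimator assumes,
with every time dependence known, so recovery can be checked against closed
forms.  Latent hazard derivative and exposure trajectory:

$$\upsilon_i(t) = \gamma_0(t) + \gamma(t)x_i(t) + q_u(t)(u_i - \bar u) +
  q_z(t) z_i, \qquad
  x_i(t) = \beta_0(t) + \beta_G(t)G_i + c_u(t)(u_i-\bar u) + c_z(t) z_i +
  \epsilon_{ix}(t),$$

with $\gamma(t) = c_\gamma t^4$ (so $\Gamma(T) = c_\gamma T^5/5$, the
oracle for all recovery tests), the quartic
$\beta_G(t) = 0.3 - 9\times 10^{-4} t - 4\times 10^{-9} t^4$, a dichotomous
Bernoulli(0.5) instrument, a Gamma(2, 1) confounder $u$ and a standard
normal covariate $z$.  The hazard rate is
$\lambda_i(t) = C_0 + \int_0^t \upsilon_i$, discretized on yearly bins
(mid-bin evaluation, floored at zero with the clipped fraction recorded);
onset is negative binomial — an individual gamma frailty (dispersion
$\theta = 20$) multiplies the yearly Poisson intensity and the first bin
with a count is the event.  The baseline is calibrated by bisection (common
random numbers, so the search is deterministic and monotone) to 15%
prevalence by age 80; the 3% and 30% robustness variants rescale the whole
latent hazard process proportionally before re-calibration, preserving the
relative effect structure at a different event density.

Design choices a reader should know, and why:

* **Effect size.** $c_\gamma = 4.5\times 10^{-11}$ puts $\Gamma(80)$ at
  $\approx 0.03$ events/person-year per exposure SD against a baseline rate
  of $\approx 0.012$ at 80 — a rate ratio near 3 for a +1 SD sustained
  exposure, comparable to strong obesity–disease relations, and large
  enough that a single cohort of $10^5$ gives a clearly resolved curve.
* **Registry ages.** Recorded event ages emulate "year of event minus year
  of birth": the onset bin is rounded up or down with probability 1/2,
  an unbiased half-year rounding.  Onsets are simulated one bin past the
  final age so the last analysis year receives both rounding halves;
  recorded ages beyond it count as censored.
* **Exposure noise.** Yearly iid trajectory noise (sd 0.3) feeds the
  hazard; assessment measurement noise (sd 0.9) does not.  Total observed
  variance is close to 1 (an SD-scale exposure).  A single undivided noise
  term of sd ~0.95 inside the hazard integral would force frequent negative
  rates at young ages and make low-prevalence scenarios unreachable;
  empirically, stable long-run adiposity plus measurement error is also the
  more realistic decomposition.
* **Centering.** $\beta_0(t) = -\mathrm{freq}\cdot\beta_G(t)$, so the
  exposure has mean zero at every age like a z-scored phenotype; the
  instrument regressions include main age terms, so this choice does not
  leak into the interaction coefficients.
* **Assessment ages** are uniform over 20–80 in the validation generator:
  the quartic must be *evaluated* over the whole follow-up range, and a
  generator whose assessments stop at 70 would make every downstream check
  hostage to polynomial extrapolation error rather than to the estimator
  under test.  (In observational cohorts with a 40–70 window that
  extrapolation is a real limitation; it lives in the instrument-fit stage
  and its delta-method bands, not in the estimator.)
* **Confounder/covariate profiles** are mild low-order polynomials
  (exposure side $0.1 - 5\times10^{-4}t$ and $0.1 + 5\times10^{-4}t$;
  outcome side $\propto(t/80)^4$ at a few $10^{-4}$/yr) producing
  confounding of the same order as the instrument effect.  All profiles are
  user-overridable functions.

What the generator deliberately does **not** emulate: linkage
disequilibrium and genotyping error, relatedness, sex-specific generative
differences (the sex column is carried but inert), time-varying covariate
*values*, delayed entry, and exposure-trajectory autocorrelation beyond the
split into a persistent genetic/confounder part and iid noise.  Passing
recovery tests on these cohorts therefore demonstrates the estimator's
correctness under its stated assumptions — not robustness to pleiotropy,
selection or latency violations, which the selection-correction module and
the sensitivity toggles probe separately.

## Numerical choices

* Jitter is Uniform(0,1) within the event year, re-drawn on exact
  collisions; yearly bins on the jittered scale collect the events of one
  recorded year, and the "last event of the year" realizes the
  largest-noise convention.  With a fixed seed the whole pipeline is
  bit-reproducible.
* The risk-set normal equations are downdated as individuals exit
  ($O((n+\mathrm{events})p^2 + \mathrm{events}\,p^3)$); a rank-deficient
  risk set raises an error naming the event time.
* The momentaneous ratio evaluates $\beta_G$ at midpoints while the
  cumulative variance evaluates it at integer ages, exactly as the formulas
  are stated; at yearly resolution the inconsistency is below 1% and is
  documented rather than resolved.
* The HP filter is solved as $(I + \lambda D^\top D)^{-1}y$ (dense solve;
  series are $\le$ 100 points), which preserves the series mean exactly and
  reproduces the input at $\lambda = 0$.
* The kernel is truncated near the boundary ages (asymmetric support); no
  boundary correction beyond local-linear's own is applied.
* The selection correction searches $\mu_k$ on a grid over $[-4, 4]$
  (step 0.01, plus a no-append candidate) and prefers, among values meeting
  the tolerance $\varepsilon = 0.005$ score-SD, the one appending fewest
  individuals.  The probit argument is the globally standardized exposure.

## Validation studies and their problem sizes

The test suite and the acceptance script re-run the validation studies at
sizes chosen to keep a full run on one CPU comfortable: 60 replicate
pipelines at $n = 10^5$ for the unbiasedness/naive-bias comparison (mean
error within Monte-Carlo error — operationalized as 3 standard errors of
the replicate mean — at $T = 40, 60, 80$; both naive estimators at least
3-fold more biased at 80); single cohorts of $n = 10^5$–$2\times10^5$ for
prevalence calibration, exponent recovery (log–log slope of
$\hat\Gamma \approx 5$, of the smoothed $\bar\gamma \approx 4$) and the
quartic-intercept check; and 500 synthetic-series replicates for the
bootstrap-coverage study (92–98% at interior ages on a linear truth).  The
slope of $\log\bar\gamma$ is the most variable of these quantities
(single-cohort SD $\approx$ 0.4–0.5): the kernel trend near the boundary
leans on the noisiest, oldest ages, where $\beta_G$ is smallest.

## Known limitations

* The instrument fit extrapolates a polynomial outside the observed
  assessment ages; in cohorts assessed only at 40–70 the young-age and
  over-75 segments inherit model-form risk (a sensitivity toggle perturbing
  the young-age segment is the recommended robustness check, and the
  estimated life-course effects of adult-onset outcomes are insensitive to
  it).
* Hazard differences can in principle cross zero; the weak-instrument floor
  refuses ratios where $|\beta_G|$ is small rather than silently clipping.
* The parametric bootstrap resamples only the $\hat\Gamma$ noise with
  independent errors; correlation induced by the shared instrument fit is
  ignored (full-pipeline resampling is available behind
  `trend` utilities but is not the default).
* Ratio-scale estimands (hazard ratios), multivariable MR with exposure
  windows, and pleiotropy-robust estimators (Egger, weighted median) are
  out of scope.
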