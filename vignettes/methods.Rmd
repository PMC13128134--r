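---
title: "Cross-world sensitivity analysis for acute biomarker changes: models and methods"
author: "copstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-world sensitivity analysis for acute biomarker changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copstrat)
```

## The problem

Some treatments move a prognostic biomarker within weeks of initiation.
SGLT-2 inhibitors in chronic kidney disease are the motivating case: they
slow long-term kidney-function decline, yet many patients show an acute
*drop* in estimated glomerular filtration rate (eGFR) about one month after
starting therapy.  The clinical question is whether a patient with a large
acute decline should expect less (or even negative) long-term benefit.

A naive regression of outcomes on the observed acute change mixes two very
different sources of variation: the causal acute *effect* of the drug, and
the change the patient would have experienced anyway (measurement error,
disease fluctuation).  `copstrat` implements a principal-stratification
analysis that separates them explicitly, at the price of one honest
admission: the data cannot identify how the two counterfactual acute
changes — $W(1)$ under treatment and $W(0)$ under control — are correlated,
because no patient is ever observed in both worlds.  That cross-world
dependence is therefore a *sensitivity parameter*, and every result is
reported as a function of it.

## Estimand

For a competing-risks endpoint (event type $e = 1$ kidney-failure-like,
$e = 2$ death-like) the target is the conditional average treatment effect
on the absolute risk by horizon $k$, given the acute change observed under
treatment:

$$\Delta_e(k \mid w_1) = \Pr[T(1) \le k, E(1) = e \mid W(1) = w_1]
                       - \Pr[T(0) \le k, E(0) = e \mid W(1) = w_1],$$

reported on the risk-reduction scale (control minus treated).  The first
term is estimable from the treated arm.  The second conditions a
control-world outcome on a treated-world biomarker and is where the causal
machinery lives.  A more formal statement of the estimand also conditions
on surviving event-free to one month (the acute change is only defined
then); with events in the first month at the per-mille level this
conditioning is dropped from the notation and the estimator, and the
package likewise does not model it.

## Model

**Biomarker regressions.**  Within each arm, the acute percent change is
regressed on baseline covariates (baseline eGFR, log proteinuria, age,
systolic blood pressure, sex, diabetes), $W(a) = X\beta^{(a)} + r^{(a)}$,
by ordinary least squares.

**Residual marginals.**  Each residual set is fitted with a Johnson SU
distribution — a four-parameter family ($\gamma, \delta$ shape; $\xi$
location; $\lambda$ scale) with unbounded support whose normal-score
transform is available in closed form:
$\epsilon = \gamma + \delta\,\mathrm{asinh}((r - \xi)/\lambda) \sim N(0,1)$
when $r$ follows the fitted law.  Percent-change residuals are visibly
skewed, which is exactly what SU accommodates and a normal margin does not.
Fitting is by maximum likelihood with quantile-based (Slifker–Shapiro)
starting values, the two positive parameters optimised on the log scale.
If the optimiser fails the package falls back to a normal marginal and
warns loudly.  An interpolated empirical cdf with Gaussian tails is
available as `residual_cdf = "empirical"` for sensitivity, but the
parametric SU cdf is the default used everywhere.

**Gaussian copula.**  The standardised residual scores
$\epsilon(0), \epsilon(1)$ are assumed bivariate normal with correlation
$\rho_\epsilon$.  Conditional on $\epsilon(1) = e_1$, the control-world
score is $N(\rho_\epsilon e_1,\, 1 - \rho_\epsilon^2)$; mapping through the
control-arm SU quantile function yields draws of the control-world acute
change given the treated-world one.  $\rho_\epsilon = \pm 1$ is handled as
an explicit degenerate branch (comonotone or antitone point mass), not as a
limit, because the analysis sweeps $\rho_\epsilon = 1$ directly.  Negative
values are supported to keep the parameter's domain honest even though the
reported sweep is $\{0.4, 0.6, 0.8, 1.0\}$.

**Outcome models.**  Within each arm, absolute risks come from a Fine–Gray
subdistribution-hazard regression (cause-specific endpoints) or a Cox model
(composite endpoint), with the biomarker entering through a restricted
cubic spline with 4 knots at the 0.05/0.35/0.65/0.95 quantiles of the
pooled two-arm acute-change distribution, plus linear covariate terms.
Coefficients are maximised by `survival` (Breslow ties; for Fine–Gray, the
`finegray` expansion with product-limit inverse-probability-of-censoring
weights); the baseline cumulative (sub)hazard is accumulated in-package by
the Breslow sum, and absolute risk is the plug-in
$1 - \exp(-\hat\Lambda_0(k)\,e^{\hat{lp}})$.

**Conditional covariate law.**  The mixture over covariates,
$f(x \mid w_1)$, is approximated by sampling-importance-resampling:
proposals draw a stratum of the dichotomous covariates with its empirical
frequency and the continuous covariates from a within-stratum multivariate
normal; each proposal is weighted by the normal density of $w_1$ at its
treated-arm regression mean (homoscedastic residual SD from the same
regression); weights are normalised and rows resampled with replacement.
Because the proposal itself estimates $f(x)$, the importance weight reduces
to $\hat f(w_1 \mid x)$ alone.  The effective sample size of the weights is
returned for diagnostics.  Strata with fewer than 5 rows are merged into
the nearest stratum (Hamming distance on the binary codes, ties to the
larger stratum) with a warning.

**Putting it together.**  For each grid value $w_1$: (i) resample covariate
rows $\hat x$; (ii) treated term: average treated-model risk at
$(w_1, \hat x)$; (iii) control term: form
$\hat r_1 = w_1 - \hat x \hat\beta^{(1)}$, its score $\hat\epsilon_1$, draw
$J$ control scores from
$N(\rho_\epsilon \hat\epsilon_1, 1 - \rho_\epsilon^2)$, map to
$\hat r_0$, set $w_0 = \hat x\hat\beta^{(0)} + \hat r_0$, and average
control-model risk at $(w_0, \hat x)$; (iv) report control minus treated.
Trials are analysed separately and pooled by relative sample size.
Pointwise 95% intervals come from a percentile bootstrap that resamples
subjects with replacement, stratified by trial and arm, and reruns the
entire pipeline — regressions, SU fits, outcome models, SIR, copula
transport, pooling — in each replicate; replicates whose fits fail are
dropped and counted, with more than 5% failures an error.  The contrast
curve against $w_1 = 0$ (does a larger decline change the effect?) is
computed inside each replicate so its intervals are valid.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `rho_eps` | cross-world residual-score correlation | sweep 0.4–1.0 | unidentifiable; the sensitivity axis |
| `k` | risk horizon (years) | 2 | standard reporting horizon for these endpoints |
| `w1_grid` | treated acute change grid (%) | −20 to 20 by 1 | range that covers the bulk of observed changes |
| `J` | copula draws per covariate row | 100 | integral approximation; error shrinks as $1/\sqrt{nJ}$ |
| `sir n_proposal` | SIR proposal draws | 10 × treated n | weight ESS stays a large fraction of n |
| `sir n_resample` | covariate rows per grid point | 1000 | balances MC error against fit cost |
| `B` | bootstrap replicates | 1000 | percentile intervals; reduce for exploration |
| spline knots | biomarker flexibility | 4 knots, pooled quantiles | standard natural-spline default |
| trim | acute-change outlier trim | 0.5/99.5 percentiles | extreme-change rows destabilise the spline tails |

## The synthetic generator

Real individual-level trial data of this kind are not redistributable, so
the package ships a generator with fully known potential-outcome structure
that emulates the pooled marginals of the large SGLT-2i kidney trials:
covariates with CKD-trial means and spreads (baseline eGFR 61.9 ± 22.3,
age 62.8 ± 9.8, SBP 137.2 ± 16.8, log proteinuria 5.6 ± 2.0, 31% female,
92% diabetic, with modest correlations and range truncation); acute-change
means −0.6% (control) and −6.4% (treated) with SD ≈ 12.7% and left-skewed
SU residuals (γ = −0.6, δ = 2.2, residual SD 12.6); latent residual scores
coupled at `rho_true`; a subdistribution mixture model for the primary
event (mass p = 0.16, time rate κ = 0.1/yr, linear predictor in the
world-specific acute change, baseline eGFR, log proteinuria and arm) and an
exponential competing hazard (0.038/yr, age and arm terms), calibrated so
control-world two-year rates sit near 4% and 6%; administrative censoring
at 3 years plus an exponential 0.02/yr.  Because the primary-cause
subdistribution is linear in $W(a)$ and the covariates the analysis
adjusts for, the estimator is correctly specified under the defaults,
enabling clean parameter-recovery and oracle tests.  `true_cate()`
evaluates the estimand directly on the truth table (both worlds known per
subject) within a bandwidth around $w_1$ — the package's identification-free
oracle.

What the generator does **not** emulate: visit schedules, informative
dropout, trial-specific covariate mixes (an all-diabetic trial appears only
via the constant-column drop path), measurement rounding, or
model-misspecified outcome surfaces.  Passing tests on this generator show
the algorithm estimates what it claims under its stated assumptions; they
do not certify robustness to violations of those assumptions.  For that,
`violate_assumption = TRUE` adds a shared frailty linking the treated-arm
residual score to the control-world event process — the no-confounding
assumption fails by construction, and the estimator is *expected* to be
biased there; it is a negative control, not a bug.

## Numerical choices

* Normal-score probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$
  before `qnorm` so extreme residuals do not produce infinities.
* One master seed; every stochastic component (SIR per grid point, copula
  draws per grid point, bootstrap replicate resampling, each generator
  block) runs on a labelled substream derived by an integer hash, so
  results are independent of grid or subject iteration order and a sub-grid
  reproduces the same values at shared points.
* The Breslow baseline treats ties by the Breslow convention throughout,
  matching the partial-likelihood tie handling.
* Horizons beyond the last event time return the risk at the last event
  time with a warning; $k = 0$ returns exactly 0.
* Degenerate designs: constant design columns are dropped with a warning
  (this is how an all-diabetic trial is handled); collinear biomarker
  regressions raise an error naming the columns; a trim interval that
  collapses to a point trims nothing.
* With an empty covariate set the SIR step is skipped (the conditional
  covariate law is trivial) and the algorithm reduces to the
  marginal-copula estimator; at $\rho_\epsilon = 1$ this reproduces the
  direct quantile-matching plug-in exactly, which is tested to $2 \times
  10^{-3}$.

## Design choices that were genuinely open

* **SU fitting criterion** — maximum likelihood (moments and percentile
  matching are less efficient at these sample sizes); alternatives are not
  benchmarked.
* **Parametric vs empirical residual cdf** in the copula transport — the
  fitted SU cdf, because the same parametric object defines the latent
  scores; the empirical mode is exposed for sensitivity only.
* **Per-trial knots** — models are fitted within trials, so knots are
  computed per trial (on its pooled two arms); trials are never pooled for
  fitting, only estimates are pooled.
* **Separate per-arm outcome fits** rather than a single interacted model:
  the algorithm calls for per-arm prediction surfaces; an interacted fit is
  a descriptive device, not part of the estimator.
* **Bootstrap stratification by trial and arm** — preserves arm sizes and
  trial composition; the method description is silent here.
* **SIR input rows from the treated arm** — the conditioning variable is
  $W(1)$, so the covariate law being approximated is the treated-arm one
  (randomisation makes the arms exchangeable at baseline, so this costs
  only efficiency).

## Problem sizes used in the shipped checks

The test suite runs the full pipeline at desk scale: oracle recovery on a
4000-per-arm trial against a 200,000-row truth table (bandwidth 1, with a
30-replicate bootstrap SE); Fine–Gray recovery over 20 replicates of
n = 2000; null calibration on two 800-per-arm trials (B = 40) plus interval
coverage over 50 repetitions of a 400-per-arm null trial with B = 200;
copula sampling checked against a rejection oracle built from 1.5 million
joint draws.  These sizes are the package's choices for routine runs; all
scale up through the ordinary arguments.

## Known limitations

* $\rho_\epsilon$ is not estimable from data — by construction.  The
  correlation-bound table (`simulate_rho_bound`) only translates candidate
  values into implied acute-effect variability so subject-matter judgment
  can exclude implausible ones.
* Absolute-risk prediction extrapolates linearly (natural-spline tails)
  beyond the observed acute-change range, with a warning but no formal
  correction.
* The SIR proposal is within-stratum Gaussian; heavily non-Gaussian
  continuous covariates would need a richer proposal.
* No left truncation, time-varying coefficients, frailty terms, or
  proportional-hazards diagnostics; eGFR-slope outcomes and joint
  multi-biomarker conditioning are out of scope.
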