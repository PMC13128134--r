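# copstrat

Copula-based principal stratification for acute biomarker changes and
long-term clinical outcomes.

## The problem

Randomized trials of SGLT-2 inhibitors in chronic kidney disease report an
acute *decline* in estimated glomerular filtration rate (eGFR) about one
month after starting treatment, even though the drugs slow long-term
progression.  Should a patient whose eGFR drops 20% in month one expect
less benefit?  Answering this causally requires knowing how the acute
change a patient showed *with* treatment, $W(1)$, relates to the change
they *would have shown* without it, $W(0)$ — and those two quantities are
never observed in the same person.

`copstrat` implements a sensitivity analysis for this cross-world problem,
for biostatisticians analysing trials where a treatment moves a continuous
biomarker early and the endpoint is a competing-risks time-to-event
outcome.

## The method

Per-arm regressions $W(a) = X\beta^{(a)} + r^{(a)}$ remove confounding
through baseline covariates; Johnson SU marginals map each residual to a
standard-normal score; the two scores are tied together by a Gaussian
copula with correlation $\rho_\epsilon$ — the unidentifiable sensitivity
parameter.  For each $\rho_\epsilon$ and each grid value $w_1$, the
conditional average treatment effect on absolute risk at horizon $k$,

$$\Delta_e(k \mid w_1) = \Pr[T(1) \le k, E(1) = e \mid W(1) = w_1]
                       - \Pr[T(0) \le k, E(0) = e \mid W(1) = w_1],$$

is estimated (and reported as a risk reduction) by combining

* Fine–Gray subdistribution-hazard fits (Cox for the composite endpoint)
  with restricted-cubic-spline biomarker effects and Breslow absolute-risk
  prediction, per arm;
* sampling-importance-resampling for the conditional covariate law
  $f(x \mid w_1)$;
* copula transport of the treated-world residual into the control world,
  $\hat\epsilon_0 \sim N(\rho_\epsilon \hat\epsilon_1, 1-\rho_\epsilon^2)$;
* sample-size-weighted pooling across trials and a stratified subject
  bootstrap for pointwise intervals.

A companion plausibility analysis (`simulate_rho_bound`) translates each
candidate $\rho_\epsilon$ into the implied variability of the individual
acute effect $W(1) - W(0)$ and the fraction of patients with an acute
*increase* beyond a threshold, so subject-matter knowledge can bound
$\rho_\epsilon$ from below.  A synthetic-trial generator with fully known
potential outcomes (`generate_trial`, `true_cate`) provides ground truth
for validation, since the real trial datasets are not redistributable.

## Worked example

```r
library(copstrat)

sim <- generate_trial(generator_config(n_per_arm = 2000, rho_true = 0.8,
                                       seed = 1))
dat <- prepare_dataset(sim$data)
#> prepare_dataset: 4000 rows in, 0 dropped for missingness, 40 trimmed,
#> 3960 retained

res <- bootstrap_cis(dat, B = 50, seed = 1, endpoint = "primary", k = 2,
                     rho_eps = 0.8, w1_grid = c(-20, -10, 0, 10, 20),
                     J = 50, sir = sir_config(n_resample = 300))
round(res$table[, c("w1", "estimate", "ci_lower", "ci_upper")], 4)
#>    w1 estimate ci_lower ci_upper
#> 1 -20   0.0072  -0.0128   0.0322
#> 2 -10   0.0025  -0.0119   0.0172
#> 3   0  -0.0031  -0.0187   0.0111
#> 4  10   0.0026  -0.0098   0.0176
#> 5  20   0.0052  -0.0057   0.0153
```

Each row is the estimated 2-year reduction in kidney-failure risk for a
treated patient whose observed month-1 eGFR change is `w1` percent,
assuming cross-world correlation 0.8, with percentile-bootstrap 95%
bounds: at this sample size the effect given a 20% acute decline is
0.007 (CI −0.013 to 0.032) — no evidence that a large decline erases the
benefit, and intervals that honestly include zero.

```r
bm <- fit_biomarker_regressions(dat)
round(simulate_rho_bound(bm, data = dat, seed = 1)[, 1:3], 3)
#>    rho_eps prop_exceeding sd_acute_effect
#> 1      0.0          0.318          16.414
#> ...
#> 9      0.8          0.146           7.297
#> 10     0.9          0.068           5.193
#> 11     1.0          0.000           0.934
```

Reading the bound table: if $\rho_\epsilon$ were 0, a third of patients
would need an acute eGFR *increase* above 1 ml/min/1.73m² under treatment
— biologically implausible — whereas $\rho_\epsilon \ge 0.8$ implies such
increases are uncommon.  That is the argument for concentrating on high
correlations.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/copstrat.R simulate --outdir out --n-per-arm 2000 --seed 1
Rscript inst/cli/copstrat.R estimate --input out/synthetic_trial.csv \
    --outdir out --endpoint primary --rho 0.4,0.8,1.0 --bootstrap 200
Rscript inst/cli/copstrat.R rho-bound --input out/synthetic_trial.csv --outdir out
```

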