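# cshcif

Flexible parametric cause-specific hazard regression and cumulative
incidence estimation for competing risks.

## The problem

In a competing-risks setting (e.g. cancer patients who may die of their
cancer or of other causes), the probability of failing from cause *j* by
time *t* — the cumulative incidence function (CIF), also called the
cause-specific cumulative probability — depends on *all* cause-specific
hazards:

    F_j(t, x) = ∫₀ᵗ S(u, x) λ_j(u, x) du,
    S(u, x)   = exp(−Σ_j Λ_j(u, x)),

so a covariate effect on one hazard does not translate directly to the
probability scale.  `cshcif` models each cause-specific hazard on the log
scale with a clamped B-spline baseline and optional time-dependent (TD)
covariate effects,

    log λ_j(t, x; β_j) = B₀(t)ᵀ γ_j + Σ_c x_c f_c(t),

fits each cause by maximum likelihood (competing events censored; the
likelihood factorizes over causes, so the joint covariance of the stacked
parameter vector is block-diagonal), and then derives:

- **individual** CIF predictions `cif_point()` / `cif_estimate()`, by
  nested Gauss-Legendre quadrature with knot-aware composite panels;
- **delta-method variances** from the analytic gradient of the CIF in the
  model parameters (`cif_gradient()`, `cif_variance()`), with
  complementary-log-log confidence intervals (`cif_ci_cloglog()`);
- **population-averaged** CIFs with a variance that accounts for the
  correlation of the individual predictions (`population_cif()`);
- **covariate-adjusted (directly standardized)** CIFs and
  **standardized risk differences** with delta-method Wald intervals
  (`adjusted_cif()`, `risk_difference()`).

It also ships the nonparametric Aalen-Johansen comparator
(`aalen_johansen()`), a competing-risks simulator (power generalized
Weibull cancer hazard, piecewise-exponential life-table other-cause
mortality; `scenario_config()`, `simulate_dataset()`, `true_cif()`), and a
Monte-Carlo study driver reporting bias, empirical and model-based
standard errors, RMSE and coverage (`run_study()`, `performance()`).

Intended users: biostatisticians and epidemiologists analysing
cause-specific time-to-event data who want smooth, covariate-resolved
cumulative probabilities with honest uncertainty, alongside the usual
nonparametric estimates.

## Worked example

```r
library(cshcif)
dat <- simulate_dataset(scenario_config(scenario = 1, N = 1000), seed = 42)
boundary <- c(0, max(dat$time))
fit <- fit_competing(list(
  cause_model_spec(1, spline_spec(degree = 3, knots = c(1, 5), boundary),
                   covariates = c("age", "sex")),
  cause_model_spec(2, spline_spec(degree = 2, knots = 1, boundary),
                   covariates = c("age", "sex"))), dat)
fit
#> Competing-risks fit: 2 cause(s), 14 parameters, total loglik = -2045.6487
#> Cause 1 hazard model: baseline degree 3 (6 df); covariates:  age (fixed), sex (fixed)
#>   8 parameters, loglik = -1438.9025, AIC = 2893.8050
#> Cause 2 hazard model: baseline degree 2 (4 df); covariates:  age (fixed), sex (fixed)
#>   6 parameters, loglik = -606.7462, AIC = 1225.4923
```

CIF for a 70-year-old woman, with delta-method standard errors and
complementary-log-log 95% intervals:

```r
cif_estimate(fit, times = c(1, 5, 10), x = c(age = 70, sex = 1))
#>   time cause estimate      se ci_low ci_high
#> 1    1     1   0.1388 0.01234 0.1165  0.1650
#> 2    5     1   0.4837 0.02290 0.4398  0.5295
#> 3   10     1   0.6093 0.02448 0.5616  0.6573
#> 4    1     2   0.0189 0.00384 0.0127  0.0281
#> 5    5     2   0.0670 0.01040 0.0493  0.0906
#> 6   10     2   0.1154 0.01657 0.0869  0.1525
```

Her estimated probability of dying from the disease (cause 1) within 10
years is 61% (95% CI 56–66%); from other causes, 12%.  The population
average over the cohort's observed covariates, with the correlation of
the individual predictions accounted for:

```r
population_cif(fit, times = c(1, 5, 10), X = dat)
#>   time cause estimate      se ci_low ci_high  setting
#> 1    1     1   0.1171 0.00934 0.1001  0.1368 observed
#> 2    5     1   0.4044 0.01522 0.3752  0.4349 observed
#> 3   10     1   0.5063 0.01643 0.4746  0.5389 observed
#> ...
```

The effect of sex on the probability scale, as a standardized risk
difference (everyone set to woman vs everyone set to man, other
covariates as observed):

```r
risk_difference(fit, times = 10, X = dat, variable = "sex",
                levelA = 1, levelB = 0, cause = 1)
#>   time cause estimate     se ci_low ci_high
#> 1   10     1     0.12 0.0309 0.0593   0.181
```

Being a woman raises the 10-year disease-specific cumulative probability
by 12 percentage points (95% CI 6–18) in this simulated cohort — the net
of the direct effect on the disease hazard and the indirect effect through
the competing hazard.

A thin command-line wrapper over the same functions is available at
`inst/cli/cshcif.R` (subcommands `simulate`, `fit`, `predict`, `adjust`,
`aj`, `simstudy`; see `?cif_cli`).

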