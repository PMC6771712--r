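---
title: "Flexible cause-specific hazard models and adjusted cumulative probabilities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible cause-specific hazard models and adjusted cumulative probabilities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cshcif)
```

## The model

For each cause $j$ among $J$ competing causes of failure, `cshcif` models
the cause-specific hazard on the log scale,

$$\log \lambda_j(t, \mathbf{x}; \boldsymbol\beta_j)
  = B_0(t)^\top \boldsymbol\gamma_j + \sum_c x_c\, f_{jc}(t),$$

where $B_0$ is a clamped B-spline basis (boundary knots repeated
degree + 1 times) for the log-baseline hazard and each covariate effect
$f_{jc}$ is either a constant (proportional cause-specific hazards) or its
own clamped B-spline expansion (a time-dependent effect).  Two
parameterization choices keep the model identified without an explicit
intercept:

* the baseline basis is a partition of unity, so it spans constants and
  absorbs the intercept;
* a time-dependent effect basis likewise spans constants and absorbs that
  covariate's time-fixed component, so a TD covariate has no separate
  proportional coefficient.

Under random censoring the competing-risks likelihood factorizes over
causes; each cause is fitted separately with all other events treated as
censored, and no assumption of independence between the competing risks
is needed for this inference.  The subject contribution for cause $j$ is

$$\ell_{ij}(\boldsymbol\beta_j)
  = -\int_0^{t_i} \lambda_j(u, \mathbf{x}_i)\,du
    + \delta_{ij} \log \lambda_j(t_i, \mathbf{x}_i).$$

Because the fits are independent, the covariance of the stacked parameter
vector $\hat{\boldsymbol\beta} = (\hat{\boldsymbol\beta}_1^\top, \ldots)^\top$
is block-diagonal with one block per cause (`competing_fit()` assembles it
with exact zeros off the diagonal).

## Estimation

The cumulative hazard has no closed form under spline log-hazards, so the
likelihood uses Gauss-Legendre quadrature: subject $i$ contributes a
$K$-node rule on $[0, t_i]$ ($K = 20$ by default; the design matrices at
the nodes are built once per fit, so each iteration is two matrix
products).

Since the log-hazard is *linear* in $\boldsymbol\beta_j$, the discretized
log-likelihood has the Poisson-regression form
$-\sum w\, e^{\mathbf{d}^\top\beta} + \sum_{events} \mathbf{d}^\top\beta$:
it is globally concave, and its gradient and Hessian are available in
closed form.  `fit_cause_model()` therefore runs a full Newton iteration
with the analytic Hessian and step halving, rather than a quasi-Newton
scheme with numerical derivatives — the analytic Hessian is exact, the
iteration typically converges in under ten steps, and the observed
information (its negative) is returned directly as the covariance.
Defaults: gradient max-norm tolerance $10^{-6}$, 200 iterations maximum,
baseline coefficients initialized at the constant-hazard moment estimate
$\log(\text{events}/\text{person-time})$ and covariate effects at 0.
Non-convergence is flagged, never silently returned; a singular
information matrix raises an error suggesting fewer knots.

Knot placement is either fixed by the user or data-driven through
`quantile_knots()`, which uses type-7 (linear-interpolation) empirical
quantiles of the event times; coincident quantile knots are an error
instructing the user to reduce the knot count.  The boundary defaults to
$[0, \max t_i]$, and predictions beyond the boundary raise a range error
rather than extrapolating a polynomial tail.

AIC ($-2\hat\ell + 2p$) drives model selection per cause
(`select_by_aic()`), with ties broken by fewer parameters, then input
order; `enumerate_td_specs()` builds the $2^q$ candidates obtained by
switching each of $q$ covariates between time-fixed and time-dependent.

## Cumulative probabilities and their variances

The cause-$j$ cumulative probability for covariates $\mathbf{x}$ is

$$F_j(t, \mathbf{x}) = \int_0^t
   e^{-\sum_{j'} \Lambda_{j'}(u, \mathbf{x})}\,
   \lambda_j(u, \mathbf{x})\,du,$$

evaluated by a *nested* Gauss-Legendre scheme: an outer rule on $[0, t]$
and, at each outer node $u$, inner rules for every cause's
$\Lambda_{j'}(u)$.  Both levels use composite panels split at the models'
internal spline knots.  This matters numerically: the integrands are only
$C^{\mathrm{degree}-1}$ at the knots, and a single panel across them loses
the rule's spectral accuracy (with cubic splines and knots at 1 and 5
years, a single 64-point panel leaves errors of a few $10^{-6}$ at
$t = 9$; 20 points per knot-delimited panel reach $\sim 10^{-10}$).  With
the composite scheme the conservation identity
$\sum_j \hat F_j(t) + \hat S(t) = 1$ holds to machine precision, and the
default panel size of $K = 20$ (32 for individual predictions) is
accurate far beyond the statistical noise; predictions are insensitive to
$K$ (the test suite demonstrates $<10^{-4}$ change between $K = 20$ and
$K = 64$).

Variances come from the multivariate delta method,
$\widehat{\mathrm{Var}}[\hat F_j] = \nabla F_j^\top \hat\Sigma_\beta
\nabla F_j$, with the *analytic* gradient in the stacked parameters.
Because $\partial \lambda / \partial \beta_k = \lambda\, d_k$ where $d_k$
is the design element, the gradient has the closed form

$$\frac{\partial F_j}{\partial \beta_{jk}} = \int_0^t S\,\lambda_j
   \Big[d_{jk}(u) - \int_0^u \lambda_j d_{jk}\Big]du,
  \qquad
  \frac{\partial F_j}{\partial \beta_{j'k}} = -\int_0^t S\,\lambda_j
   \int_0^u \lambda_{j'} d_{j'k}\,du,$$

which the engine discretizes on exactly the same nodes as the point
estimate — so the analytic gradient is the exact derivative of the
computed estimate and matches central finite differences to near machine
precision (a property the test suite checks directly).  Negative
variances can only arise from floating-point noise and are clipped to
zero with a warning.

Confidence intervals are computed on the $\log(-\log(1-F))$ scale and
back-transformed as $1 - (1-\hat F)^\Omega$ with
$\Omega = \exp\{\pm z_\alpha\,\mathrm{se}_{\mathrm{cloglog}}\}$.  The
transform is deliberately applied to the *complement* $1 - F_j$: for rare
events or early follow-up $F_j$ is near 0 and the denominator
$F \log F$ of the direct transform degenerates, while $1-F$ stays far
from 0.  (The source literature prints the back-transform applied
directly to $F_j$ while describing the complement-based construction in
the text; this package follows the construction, which also guarantees
bounds in $(0,1)$ containing the estimate.)  Degenerate estimates
($F \in \{0, 1\}$) return a point interval with a warning.

### Population, adjusted and contrasted curves

The population curve is the weighted mean
$\hat F^P_j(t) = \sum_i w_i \hat F_j(t, \mathbf{x}_i)$ (weights default
to $1/N$ and are exposed so curves can be standardized to a subsample,
e.g. the treated, or an external reference population).  Its variance is
$(\mathbf{G}\mathbf{w})^\top \hat\Sigma_\beta (\mathbf{G}\mathbf{w})$
with $\mathbf{G}$ the $m \times N$ matrix of individual gradients — the
individual predictions are strongly correlated because they share
$\hat{\boldsymbol\beta}$, and this quadratic form accounts for that.  The
engine accumulates $\mathbf{G}\mathbf{w}$ directly (everything is
evaluated for all subjects simultaneously as nodes-by-subjects matrices),
never materializing $\mathbf{G}$; a test verifies equality with the
explicit matrix-algebra formula assembled from per-subject gradients.

`adjusted_cif()` implements direct standardization: every subject's value
of one covariate is overwritten with a fixed level, the rest kept as
observed, and the population machinery is applied.
`risk_difference()` contrasts two levels, $D(t) = F^{Adj}_j(t, A) -
F^{Adj}_j(t, B)$; its gradient is the difference of the two weighted
gradient vectors against the same $\hat\Sigma_\beta$, so the correlation
between the two standardized curves is retained.  The interval for
$D(t)$ is Wald on the identity scale — differences are signed, so the
cloglog transform does not apply.

## The nonparametric comparator

`aalen_johansen()` implements the standard estimator
$\hat F_j(t) = \sum_{s \le t} \hat S(s^-) d_{js}/n_s$ with all-cause
Kaplan-Meier survival, events preceding censorings at tied times, and the
Aalen-type (Dinse-Larson) variance.  The conservation identity holds
exactly by construction; point estimates are cross-checked against
`cmprsk::cuminc` in the tests, while the variance is validated by its
replicate behaviour (exact agreement with any particular package's
internals is not claimed).

## The simulator

`scenario_config()` encodes two study designs mimicking a cancer cohort:

| parameter | scenario 1 | scenario 2 |
|---|---|---|
| cancer baseline $(\kappa, \rho, \alpha)$ | $(2, 1.2, 0.1)$ both sexes | men $(2, 0.4, 0.2)$, women $(2, 0.3, 0.2)$ |
| $\beta_{\text{Age}}$ (per year) | 0.03 | 0.03 |
| $\beta_{\text{Sex}}$ | 0.3 | 0 (TD effect via sex-specific baselines) |
| P(woman) | 0.5 | 0.3 |
| age classes | $[30,65), [65,75), [75,80)$ with probs 0.25/0.35/0.40, uniform within | same |
| year of diagnosis | U(2000, 2003), generated but not modeled | same |
| other-cause mortality | life table, piecewise exponential | same |
| dropout | Exp(0.035) | same |
| administrative censoring | 10 years | same |

The cancer baseline is the **power generalized Weibull** hazard
$\lambda_0(t) = \kappa\alpha\rho^\kappa t^{\kappa-1}
(1+(\rho t)^\kappa)^{\alpha-1}$, whose closed-form cumulative hazard
$(1+(\rho t)^\kappa)^\alpha - 1$ makes inverse-transform sampling exact
(the round-trip identity is tested to $10^{-10}$).  With
$(2, 1.2, 0.1)$ the hazard has the characteristic sharp peak inside the
first year (mode at $t \approx 0.93$) followed by a long decline — the
shape that makes a flexible baseline necessary and a quadratic spline
visibly too stiff.

Two design choices deserve explicit justification:

* **Age centering.**  Age enters the linear predictor as
  $\beta_{\text{Age}}(\text{age} - 65)$.  Uncentered age would scale the
  baseline by $e^{0.03 \cdot \text{age}} \approx 7$–$10$, pushing
  10-year disease-specific probabilities above 0.9 and censoring below
  10% — nothing like a realistic elderly cancer cohort.  Centering at 65
  years puts the population 10-year probabilities near 0.50 (cancer) and
  0.17 (other causes) and the overall censoring near 38%, the levels a
  cancer-registry statistician would expect for this design, with about
  15% lost to follow-up from the dropout process.
* **Synthetic life table.**  `synthetic_life_table()` generates
  Gompertz-shaped annual mortality rates per sex
  ($h = A_s e^{B_s \cdot \text{age}}$, anchored at 0.010/0.006 at age 60
  and 0.065/0.045 at age 80 for men/women), constant over calendar years.
  It reproduces the order of magnitude and age-gradient of early-2000s
  European population mortality, not any national vintage; analyses
  needing real rates can supply them via `read_life_table()`.

Other-cause times are sampled piecewise-exponentially with the rate
updating at every attained-age and calendar-year boundary; the exact
piecewise-linear cumulative hazard is also used (not quadrature) inside
`true_cif()`, which computes the generating-model cumulative
probabilities for any covariate sample by Gauss-Legendre integration of
$\lambda_j S$ with closed-form $\Lambda_1$ and exact $\Lambda_2$.

What the simulator does **not** emulate: delayed entry or left
truncation, covariate measurement error or missingness, informative
censoring, more than two causes in the shipped scenarios (the fitting and
prediction API supports any $J \ge 2$), and real national life-table
vintages.  Passing simulation tests therefore demonstrate correctness of
the estimator under the stated generating mechanisms, not robustness to
those complications.

`make_mgus_fixture()` generates a fully synthetic monoclonal-gammopathy
cohort (rare progression to plasma cell malignancy competing with common
death, Gompertz death hazard in attained age) for end-to-end pipeline
tests; its generating model is documented in its help page and makes no
claim to reproduce any real cohort beyond qualitative shape.

## The Monte-Carlo study driver

`run_study()` simulates replicates, fits each requested model
(`study_model()` definitions expand per replicate, with the spline
boundary set to the observed follow-up range), computes population
cumulative probabilities at the requested times — optionally within
covariate-defined subsets such as women only — and summarizes each cell
with `performance()`: bias, relative bias, empirical SE (divisor
$n_{sim}-1$), model SE $\sqrt{\overline{\widehat{\mathrm{Var}}}}$, RMSE
and the coverage of the cloglog interval.  `acceptable_coverage_range()`
gives the Monte-Carlo acceptability band
$p \pm 2\sqrt{p(1-p)/n_{sim}}$ (e.g. $[0.931, 0.969]$ for 95% and 500
replicates).

**Per-replicate truth.**  Each replicate is evaluated against the
generating-model probability standardized to *that replicate's own*
covariate sample, and the summaries are computed on the error scale
$\hat\theta_r - \tilde\theta_r$ (for a common truth this reduces to the
usual definitions).  The alternative — one fixed truth from a large
covariate sample — mixes into the empirical error the variance of the
covariate draw itself, $\mathrm{sd}(F_i)/\sqrt{N}$, which the
delta-method interval does not (and should not) cover, since it
conditions on the covariates.  Under this package's generator that
component is large enough to deflate measured coverage by about two
Monte-Carlo standard errors at $N = 1000$ for the common cause, purely as
an artifact of the evaluation.  Per-replicate truth evaluates the
interval against the estimand it actually targets; it also makes the
identity $\mathrm{RMSE}^2 = \mathrm{bias}^2 +
\mathrm{empSE}^2 (n_{sim}-1)/n_{sim}$ exact, which the tests assert on
every produced row.

Non-convergent replicates are excluded and counted; more than 5%
non-convergence for any model aborts the study (in practice
non-convergence is essentially absent under the shipped scenarios).

**Problem sizes.**  The shipped experiments use $n_{sim} = 500$
replicates at $N \in \{300, 1000\}$ for the proportional-hazards scenario
and $n_{sim} = 150$ at $N = 1000$ for the TD-misspecification contrast;
at these sizes the 2% relative-bias check sits at roughly three
Monte-Carlo standard errors for the least favourable (other-cause) cells,
so a pass is informative rather than lucky.  These were chosen as the
package's own trade-off between resolution and runtime; they complete in
a few minutes on one CPU.

## Known limitations

* No delayed entry / left truncation; follow-up must start at time 0.
* No shared frailty or random effects; no interval censoring.
* Model-selection uncertainty (AIC over the $2^q$ TD enumeration) is not
  propagated into the delta-method variances, matching standard practice;
  bootstrap would be needed for selection-aware inference.
* Predictions are clamped to the spline boundary (the maximum observed
  follow-up by default); long-range extrapolation beyond the data is
  deliberately refused rather than polynomial-extended.
* The cloglog interval degenerates to a point when $\hat F \in \{0,1\}$
  (it warns); this occurs only at times with no events at risk.
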