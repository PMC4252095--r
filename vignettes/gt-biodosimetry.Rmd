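---
title: "High-dose dicentric biodosimetry with a Gompertz-type weighted-Poisson model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-dose dicentric biodosimetry with a Gompertz-type weighted-Poisson model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtdose)
```

## The problem

Dicentric chromosomes are the gold-standard biological dosimeter: their
background frequency is nearly zero and their yield rises steeply with
absorbed dose. Standard calibration curves, however, cover 0–5 Gy.
Beyond that, cells carrying heavy damage rarely reach metaphase, and when
caffeine is used to abrogate the G2/M checkpoint so that they do, two
things happen to the count data:

* the yield saturates — a human cell has 46 centromeres, so the supply of
  material for centromere-bearing aberrations is intrinsically limited —
  and linear or linear-quadratic curves overshoot badly at high doses;
* the distribution of dicentrics among cells becomes **underdispersed**
  (dispersion index below 1), while every classical partial-body tool
  assumes Poisson counts and diagnoses exposure heterogeneity through
  *over*dispersion.

`gtdose` implements an integrated model for both phenomena, together with
the classical linear/linear-quadratic machinery it is compared against.

## The count model

Dicentrics per cell follow a weighted Poisson distribution: a Poisson(λ)
pmf multiplied by the increasing weight $w(k) = 1 + b\,k^2$ and
renormalized,

$$P(X = k) = \frac{e^{-\lambda}\lambda^k\,(1 + b k^2)}
  {k!\,\bigl[1 + b\lambda(1+\lambda)\bigr]},\qquad
  \lambda > 0,\; b \ge 0 .$$

The weight acts as a sighting mechanism that favours cells with many
dicentrics. At $b = 0$ the distribution is exactly Poisson(λ) — this is
the whole-body zero-dose case. The normalizer and the first two moments
are closed forms (`wpois_norm()`, `wpois_mean()`, `wpois_var()`):

$$E(X) = \lambda\,\frac{1 + b(\lambda^2 + 3\lambda + 1)}
  {1 + b\lambda(1+\lambda)},\qquad
  E(X^2) = \frac{\lambda(1+\lambda) + b\lambda(\lambda^3 + 6\lambda^2 +
  7\lambda + 1)}{1 + b\lambda(1+\lambda)} .$$

Because $\log w$ is convex near $k=0$ and concave in the tail, the family
is not locked into one dispersion regime: its dispersion index reaches
values slightly above 1 (about 1.08 at, e.g., λ = 1, b = 0.1) and drops
well below 1 where the data demand it. This is an empirical device for
modelling underdispersed counts, not a mechanistic explanation of the
underdispersion. Mixed-Poisson families (and hence the semi-empirical
multiparametric alternatives built on them) are always overdispersed and
cannot play this role, which is why this weighting approach is used
instead.

```{r dispersion}
wpois_var(1, 0.1) / wpois_mean(1, 0.1)      # mild overdispersion
wpois_var(4.32, 10.6) / wpois_mean(4.32, 10.6)  # strong underdispersion
```

Numerical notes: the pmf is evaluated in the log domain
(`dpois(log = TRUE) + log1p(...)`) so large $b\lambda$ cannot overflow;
the model support is unbounded (the biological ceiling of 23 dicentrics
from 46 centromeres is a property of the data, not the model), and series
computations — used only as cross-checks and for sampling — are truncated
when the geometric tail bound falls below tolerance, with a hard cap at
k = 500. Sampling is by inverse CDF on the cumulative pmf; the support is
small in practice (< 50), so no rejection scheme is needed.

## The dose–response

The rate follows a Gompertz curve of dose,
$\lambda(d) = \beta_0 e^{-\beta_1 e^{-\beta_2 d}}$, and the weight grows
linearly, $b(d) = \beta_3 d$ — with no intercept, so an unexposed sample
is purely Poisson. The predicted yield $\hat Y(d)$ is the weighted-Poisson
mean at $(\lambda(d), b(d))$: a bounded sigmoid ("Gompertz-type", GT).
The parameters, with units:

| parameter | meaning | unit |
|---|---|---|
| $\beta_0$ | saturation rate (upper asymptote of λ) | dicentrics/cell |
| $\beta_1$ | log-drop of the rate at dose 0, $\lambda(0)=\beta_0 e^{-\beta_1}$ | — |
| $\beta_2$ | rate of approach to saturation | Gy⁻¹ |
| $\beta_3$ | growth of the underdispersion weight | Gy⁻¹ |

`gt_fit()` maximizes the cell-level log-likelihood
$\sum_d\sum_k n_{d,k}\log P(k;\lambda(d), b(d))$ with BFGS on
log-transformed parameters (enforcing positivity; estimates are reported
on the natural scale), from five dispersed deterministic starts —
including a near-Poisson start with $\beta_3 \approx 0$ — keeping the best
converged optimum; the per-start objective values are retained in the fit
so the no-regression property is checkable. The covariance is the inverse
numerical Hessian at the optimum, with an SVD pseudo-inverse fallback
(flagged) if the information matrix is singular. Convergence tolerance is
1e-12 on the relative objective.

```{r fit}
cal <- read_distribution_table(
  system.file("extdata", "calibration_dicentrics.tsv", package = "gtdose"))
fit <- gt_fit(cal)
coef(fit)
attr(chi2_goodness(cal, fit), "total")
```

The classical curves (`classical_fit()`) use identity-link Poisson ML on
the per-dose totals. Two wrinkles, both deliberate:

* with a free intercept the identity-link likelihood is undefined at dose
  0 (the mean is the intercept itself, and the sole background dicentric
  forbids $C \le 0$), so the intercept variant is fitted on positive
  doses; if $\hat C < 0$ — which is what happens on high-dose calibration
  data — the curve is automatically refitted without the intercept and
  the event recorded;
* without an intercept the linear model has the closed-form score
  solution $\hat\alpha = \sum X_d / \sum N_d d$ (zero-dose rows enter
  only through the totals).

Published coefficients can be wrapped with `classical_curve()` when a
dose must be estimated against an externally fitted curve.

## Dose estimation

Given an observed yield $Y_0$ with standard error $SE(Y_0)$ (the
empirical $\sqrt{Var/N}$, not the Poisson $\sqrt{Y/N}$ — the former is
what published SE columns report and is robust to the
under/overdispersion at issue), the point dose solves
$\hat Y(d) = Y_0$ by Brent root finding on [0, 100] Gy; yields above the
curve ceiling raise a saturation error. Confidence limits follow the
inverse-regression (Merkle) construction: with the simultaneous band
$\hat Y(d) \pm R\,s(d)$, where $s(d)$ is the delta-method prediction SE
and $R = \sqrt{\chi^2_{0.95,p}}$ for $p$ fitted parameters (3.0802 for
the GT curve, following the parameter count of whichever curve is used),

$$d_L:\; \hat Y(d) + R\,s(d) = Y_0 - z\,SE(Y_0),\qquad
  d_U:\; \hat Y(d) - R\,s(d) = Y_0 + z\,SE(Y_0) .$$

This combination is the package default; `combine = "band"` or
`"yield"` isolate either uncertainty source. For a sample with no
dicentrics at all the empirical SE collapses to zero, so the upper yield
bound falls back on the exact Poisson 97.5% limit $3.69/N$ and the
estimate is dose 0 with an upper limit only.

**Partial-body exposures.** A partial exposure mixes irradiated cells
with unirradiated ones, inflating the zero class. Because the underlying
distribution is underdispersed, the inflation may fail to push the
dispersion index above 1 at high irradiated fractions — the u-test must
be read with caution, so `partial_body_dose()` warns rather than refuses
when u is not significant. Two estimators are provided:

* `partial_body_dose()` fits the zero-truncated weighted Poisson to the
  cells with ≥ 1 dicentric (the inflated zero class carries no
  information under truncation), then reports the *untruncated* mean at
  $(\hat\lambda, \hat b)$ as the irradiated-fraction yield, with a
  delta-method SE from the truncated fit's information matrix, and
  inverts the GT curve at that yield. For strongly truncated samples the
  profile likelihood can be flat in $b$ toward $+\infty$ (the limiting
  pmf $\propto k^2 \lambda^k/k!$ is well defined); the fit then flags the
  boundary and uses a pseudo-inverse — the yield and its SE remain well
  determined.
* `dolphin_dose()` is the classical contaminated-Poisson estimator: the
  irradiated-fraction yield solves $Y_F/(1-e^{-Y_F}) = X/(N-n_0)$ and
  the irradiated cell fraction is $(X/Y_F)/N$. It requires an actual
  zero-class excess ($X/(N-n_0) > 1$). Its yield SE is a
  ratio-estimator delta method on $X/(N-n_0)$ over i.i.d. cells,
  propagated through the inverse of $h(Y)=Y/(1-e^{-Y})$ — a package
  choice, since only the point estimator is classical.

```{r dose}
part <- dicentric_dist(c(201, 8, 34, 28, 19, 7, 1, 0, 1, 0, 1))
partial_body_dose(part, fit)
```

## The simulator

`simulate_whole_body()` draws cell-level counts from the weighted Poisson
at $(\lambda(d), b(d))$; `simulate_partial_body()` irradiates each cell
with probability $f$ and scores zero otherwise. It emulates the study
conditions the calibration reflects: the bundled 11-dose design (2000
cells at the lowest doses down to 100 at 15–25 Gy) and mixing fractions
of 30% and 70% at 6 and 12 Gy. One global seed expands into per-dose
substreams keyed by position, so extending a design never reshuffles
existing draws. The simulator reproduces scoring-level randomness only:
it does not model cell-cycle delay, mitotic-index selection, scorer
variation, inter-donor differences or caffeine pharmacodynamics, so
passing recovery and coverage tests demonstrate internal consistency of
the estimators under the model — not robustness to those real-data
effects.

Test problem sizes are deliberately desk-scale: recovery checks use the
calibration design itself (8 250 cells per replicate, 10 replicates) and
zero-truncated recovery uses 5 000 cells, which keeps the full suite
under a minute while leaving Monte-Carlo error far smaller than the
3-SE acceptance envelope.

## Design choices where the design was open

* **Weight form.** The quadratic weight $1 + bk^2$ with closed-form
  normalizer $1 + b\lambda(1+\lambda)$ is the family implemented
  throughout; it reproduces the published calibration fit, the per-dose
  goodness-of-fit column and the downstream dose estimates of the study
  this package operationalizes, and it is the unique simple increasing
  weight we found that is exactly Poisson at $b=0$ yet reaches both
  dispersion regimes.
* **χ² aggregation** is per dose over dicentric totals, not per count
  class — the form that matches the published goodness-of-fit tables;
  doses with structurally zero expectation are excluded from the sum.
* **Merkle combination.** How the band and the yield uncertainty combine
  is not uniquely determined by the inverse-regression idea; the default
  above was selected because it reproduces published whole- and
  partial-body confidence intervals to 0.01 Gy, and it remains a
  configurable option.
* **Degenerate inputs.** Ties in root finding cannot occur (the GT yield
  is strictly increasing wherever the band is evaluated); yields below
  $\hat Y(0)$ clamp to dose 0; saturated yields error out rather than
  extrapolate.

## Limitations

* The calibration data behind the bundled tables come from caffeine
  treated, 57-h cultures of a single donor per purpose and ¹³⁷Cs γ rays;
  the fitted coefficients should not be transported to other culture
  protocols, LETs or dose rates.
* The GT curve is empirical. Its low-dose behaviour trades accuracy
  against the 0.1–3 Gy region for stability up to 25 Gy; below ~3 Gy a
  conventional linear-quadratic curve on conventional cultures remains
  the better tool.
* The u-test loses its usual screening power under underdispersion;
  partial-body analysis should be triggered by accident circumstances or
  clinical signs, not the u statistic alone.
* Dose-rate effects, protracted exposures (G-function corrections) and
  survival-corrected fraction estimates are out of scope.
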