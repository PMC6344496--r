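---
title: "Modelling lifespan performance trajectories with imapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lifespan performance trajectories with imapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imapr)
```

## The model and its assumptions

`imapr` treats measured performance — sprint speed, grip strength, chess
rating, wheel-running distance — as the product of how many cells an
organism has and how well they work:

$$P(t) = \beta(t)\,N(t), \qquad \frac{dN}{dt} = \alpha(t)\,N(t).$$

Two assumptions close the system. First, replicative senescence makes
the per-capita growth rate decay exponentially,
$\alpha(t) = \alpha_0 e^{-\alpha_r t}$, so the population saturates at
$N_\infty = N_0 e^{\alpha_0/\alpha_r}$ rather than growing without
bound. Second, average cell functionality declines as
$\beta(t) = \beta_0\,(1 - e^{\beta_r (t - t_d)})$: the loss accelerates
with age and crosses zero exactly at an explicit time of death $t_d$.
The solution is a product of a saturating rise and an accelerating
decline,

$$P(t) = \beta_0 N_0 \, e^{\frac{\alpha_0}{\alpha_r}(1 - e^{-\alpha_r t})}
        \left(1 - e^{\beta_r (t - t_d)}\right),$$

which is an inverted-U with $P(t_d) = 0$. The curve is deliberately
averaged: cell types, their individual contributions and cell renewal
are all folded into the two rate functions. A general multi-type
variant ($P = \sum_i \Phi_i \beta_i N_i$ with per-type rates, integrated
numerically) is provided as `multitype_performance()`; with a single
averaged type it collapses to the closed form, which the tests verify
at relative tolerance $10^{-6}$.

Dividing age by lifespan, $u = t/t_d$, removes the units:

$$x(u) = e^{-\frac{\alpha_0^*}{\alpha_r^*} e^{-\alpha_r^* u}}
        \left(1 - e^{\beta_r^*(u-1)}\right),
  \qquad \alpha_0^* = \alpha_0 t_d,\;
         \alpha_r^* = \alpha_r t_d,\;
         \beta_r^* = \beta_r t_d,$$

with normalisation $P(t) = \beta_0 N_\infty\, x(t/t_d)$. All fitting
happens in the five-parameter set
$(\mathrm{scale}_\infty, \alpha_0^*, \alpha_r^*, \beta_r^*, t_d)$: after
nondimensionalisation every shape parameter is $O(1{-}10^2)$ across
species as different as mice ($t_d \approx 2.5$ y) and humans
($t_d \approx 120$ y), which conditions the least-squares problem far
better than the raw rates (for the 100 m series,
$\beta_r \approx 0.018\,\mathrm{y}^{-1}$ versus $\beta_r^* = 2.19$).

The Moore reference curve $P(t) = a(1-e^{-bt}) + c(1-e^{dt})$ is the
established empirical description of the same pattern; it lacks a death
time. The Siler mortality hazard
$q(t) = a_1 e^{-b_1 t} + a_2 + a_3 e^{b_3 t}$ is included because
substituting an age-dependent mature hazard
$a_2(t) = a_1 + a_3 - 2a_1 e^{-b_1 t} - 2a_3 e^{b_3 t}$ turns it exactly
into the Moore form — the structural bridge between mortality modelling
and performance modelling. This identity is tested to machine precision
on 1000 random parameter sets.

## Parameters that matter

| parameter | units | meaning | typical values |
|---|---|---|---|
| $\alpha_0^*$ | — | initial growth rate × lifespan | 22–68 (humans), up to 1125 (thoroughbred) |
| $\alpha_r^*$ | — | strength of growth saturation × lifespan | 16–26 (humans), 160 (mice) |
| $\beta_r^*$ | — | steepness of the terminal decline | ≈2–6; ≪1 means a near-linear decline |
| $t_d$ | years | explicit time of death | ≈95–185 y (human series) |
| $\mathrm{scale}_\infty$ | performance units | $\beta_0 N_\infty$, overall scale | data-dependent |

Derived quantities: the **age of peak performance** is the unique
interior maximiser of $x(u)$. Setting $d\log x/du = 0$ gives the
stationarity condition

$$\alpha_0^* e^{-\alpha_r^* u}
  = \frac{\beta_r^* e^{\beta_r^*(u-1)}}{1 - e^{\beta_r^*(u-1)}},$$

whose left side is decreasing and right side increasing on $(0,1)$, so
any sign change brackets a unique root; `peak_age()` solves it with
`uniroot()` at absolute tolerance $10^{-8}$ on $u$, falling back to a
dense-grid argmax if bracketing fails, and reports monotone curves as
degenerate boundary cases. The **normalised peak** $u^* = t_{peak}/t_d$
depends only on the three shape parameters — a scale-free measure of how
early in life performance peaks (around 20% of lifespan across the
packaged series). The **time constant** $\tau = 1/\alpha_r = t_d /
\alpha_r^*$ measures how fast growth saturates and is comparable to
organismal growth-curve timescales.

## From raw records to the fitting target

Raw data are per-individual performances at an age, discretised in the
unit natural to the species (years for humans, months for racing
dogs/horses, weeks for mice and mouse lemurs). `top_envelope()` groups
records into half-open bins $[kw, (k+1)w)$ and keeps the per-bin
maximum — the top-performance envelope that all fits target. "Envelope"
here means per-age maximum, not a geometric convex hull; an optional
`upper_concave_hull()` post-process provides the stricter geometric
reduction for sensitivity analyses but is off by default. Bin ages are
reported at bin centers (half-open bins avoid double-counting boundary
ages) converted to years: months divide by 12, weeks by 52.1775 — the
years-of-life convention, configurable. Sparse late-age bins are kept
as-is, not merged.

## Fitting, numerically

`fit_imap()` and `fit_moore()` minimise unweighted least squares with
the Levenberg–Marquardt implementation in `minpack.lm::nls.lm`, under
positivity bounds ($10^{-6}$ to $10^4$ for shape parameters) and
$t_d \in (\max t,\, 50 \max t)$. Per-bin record counts can be supplied
as weights but are off by default. The default start —
$\alpha_0^* = 30$, $\alpha_r^* = 20$, $\beta_r^* = 3$,
$t_d = 1.2\max(t)$, $\mathrm{scale}_\infty = 1.05\max(y)$ — sits in the
middle of the human range of the packaged series; an optional
multi-start (`n_starts`, log-normal jitter with sd 0.3 on a fixed seed)
guards against local minima, which matter mostly for the weakly
identified Moore amplitudes. Optimisation uses the *unclamped* curves
(negative values past $t_d$ keep the objective smooth); reporting and
prediction clamp at zero with a flag, since performance is non-negative
by definition.

The parameter covariance is $\hat\sigma^2 (J^\top J)^{-1}$ with a
central-difference Jacobian of the model curve at the optimum (pseudo-
inverse fallback when $J^\top J$ is singular). Goodness of fit:
$R^2$, adjusted $R^2$, RMSE, and AICc computed as
$n\ln(SS_{res}/n) + 2k + 2k(k+1)/(n-k-1)$ with $k$ counting the curve
parameters plus the error variance — the standard small-sample
convention, applied identically to both models so that $\Delta$AICc is
internally consistent (only its sign should be treated as portable
across AICc conventions). `compare_models()` adds the dynamic
time warping distance between the two fitted curves: classic
dynamic-programming DTW with absolute-difference cost, symmetric steps
and no window, implemented here directly since it is a first-class
comparison primitive of the package.

## Credibility envelopes

`sample_parameters()` draws from the multivariate normal defined by the
estimates and covariance (default 100,000 draws); draws violating
positivity are rejected and redrawn so the requested count is exact,
with the rejection rate logged and a hard failure above 50% (a
covariance that wide is inconsistent with the parameter domain).
`credibility_envelope()` evaluates the curve for every draw and takes
pointwise min/max — the envelope containing *all* iterations, not a
quantile band (a 2.5/97.5% quantile option exists for practical use).
Curves are clamped at zero before enveloping. Because every drawn
integrative-model curve dies at its own $t_d$, the envelope closes to
zero width beyond the largest drawn death time; Moore envelopes, lacking
the parameter, widen monotonically past the peak across the observed age
range. Note that at extreme extrapolations (well past any plausible
lifespan) the clamped Moore draws also all reach zero, so the divergence
contrast is assessed over the data span and a modest extension.

## Synthetic data

No raw performance records are redistributable, so the package ships
the published parameter table for the 17 series
(`series_fixtures()`) and generates data from it. Two generators:

* `simulate_envelope()` — envelope values with multiplicative Gaussian
  noise (default 1%, the scale consistent with the near-0.99 adjusted
  $R^2$ of the densest human series), on a default grid of 100 ages
  spanning 1–80% of the lifespan, matching the observed span of the
  collected series (ages beyond $t_d$ are clamped and flagged).
* `simulate_population()` — ranking-style cohorts: per age bin,
  `n_per_age` individuals at `curve × (1 − |δ|)`, δ ~ N(0, 0.05), so
  every record sits at or below the top-performer curve and the bin
  maximum converges to it as the cohort grows (an extreme-value
  structure like real federation rankings).

What the generators do *not* emulate: secular trends (year-of-event
effects), sex interactions, heteroscedastic age-dependent noise, and
the severe late-age sparsity of real master's-athlete data. Passing
recovery tests on these simulations therefore demonstrates the
estimator's correctness under the stated noise models, not robustness
to every artefact of scraped ranking data.

The fixture table carries a computed `peak_consistent` flag: the
published peak age of each series is recomputed from its published
shape parameters, and rows that disagree by more than 0.15 years are
flagged rather than asserted. The sprint, chess and mouse-lemur rows
reproduce to two decimals; the shotput, weightlifting, marathon and
some long-distance rows do not (their printed peaks are not consistent
with their printed parameters), and the greyhound peak appears to be
printed in different units than its lifespan. The flags keep these
documented inconsistencies out of the test anchors. Similarly, the
published "corrected lifespan" variant of the facial-recognition series
(peak 30.63 y at $t_d = 122$) stems from a refit of unavailable raw
data and cannot be derived from the printed parameters; it is treated
as an input where needed, not recomputed.

## Design choices and limitations

* **Age origin.** The model is anchored at $t_0 = 0$; the earlier "first
  cellular division" time is not representable and all fits share this
  convention.
* **Tolerances.** Root-finding at $10^{-8}$ on $u$ and cross-form
  agreement at $10^{-12}$ are appropriate because everything is $O(1)$
  after nondimensionalisation.
* **Problem sizes.** The packaged tests run the recovery study at 50
  replicates × 100 ages × 1% noise and the credibility contrast at
  10,000 draws — sizes chosen to exercise the asymptotics the methods
  rely on while keeping the default suite fast; the user-facing
  defaults (100,000 draws) match the published Monte-Carlo design.
* **Weak identifiability.** When data stop well before the decline
  (facial recognition, strength events), $t_d$ and $\beta_r^*$ are
  poorly determined jointly — expect wide covariances and occasional
  boundary solutions; the multi-start option and the credibility
  envelope make this visible rather than hiding it.
* **The model is averaged and deterministic.** It describes the
  top-performance envelope of a population, not individual
  trajectories, and its parameters summarise bulk cellular dynamics;
  mechanistic attribution (telomeres, metabolic waste) is narrative,
  not fitted.
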