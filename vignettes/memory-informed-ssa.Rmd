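---
title: "Memory-informed step-selection analysis with stepmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory-informed step-selection analysis with stepmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepmem)
```

## The model

Step-selection analysis (SSA) models animal movement in discrete time as a
sequence of choices. At each fix the probability of ending the next step at
location $s_t$, given the history $H_{t-1}$ of previously visited locations,
factors into a *selection-free movement kernel* $k(s_t \mid H_{t-1};
\beta_m)$ — how the animal would move with no preferences — and a
*movement-free selection function* describing its preferences:

$$
p(s_t \mid H_{t-1}) \;=\;
\frac{k(s_t \mid H_{t-1};\beta_m)\;
      e^{\beta_w^\top r(s_t)}\; e^{\beta_f^\top f(s_t)}}
     {\sum_{s' \in U} k(s' \mid H_{t-1};\beta_m)\;
      e^{\beta_w^\top r(s')}\; e^{\beta_f^\top f(s')}}
$$

where $r(s)$ are environmental covariates with selection coefficients
$\beta_w$, and $f(s)$ are **familiarity covariates** — functions of the
animal's own movement history — with coefficients $\beta_f$. Because the
familiarity term is exponential-linear, the whole model stays inside the
standard SSA machinery: discretize the denominator with a used step plus
matched "available" steps drawn from the kernel, and estimate all
coefficients by conditional logistic regression. A positive familiarity
coefficient means that, offered two equally accessible and otherwise
identical locations, the animal prefers the familiar one — the statistical
signature of spatial memory, subject to the usual caveat that unmeasured
habitat drivers can masquerade as familiarity.

The kernel uses exponential-family distributions so that this reduction
works exactly: gamma step lengths and von Mises turning angles with mean
direction zero. `fit_tentative()` estimates these once from the observed
steps (the tentative-kernel convention); `build_design(movement_adjust =
TRUE)` optionally adds the $\log(sl)$, $sl$, $\cos(ta)$ adjustment terms
that absorb the bias of tentative parameters.

## Familiarity covariates

The package constructs every familiarity covariate in common use:

* **Occurrence distributions (OD).** `occurrence_distribution()` evaluates
  an isotropic Gaussian kernel density of the fixes in a chosen time window
  at grid-cell centers and normalizes it to a probability surface. The
  window is the memory model: a short window (e.g. the last 3 days) is an
  abrupt-forgetting working memory, an ever-growing window a never-forget
  reference memory. Case studies in the literature often estimate ODs with
  continuous-time conditional densities or biased random bridges; the
  selection model consumes the OD generically, so this package deliberately
  uses the simpler Gaussian KDE and documents that substitution. The
  default bandwidth recommendation is `max(res, 0.5 * median(sl))`.
* **Contour indicators.** `od_contour_indicator()` marks the smallest set
  of cells holding a stated fraction (e.g. 95%) of OD mass — the binary
  "was this inside last season's range" covariate. Ties in density are
  broken by cell index so the surface is deterministic.
* **Diel stratification.** `stratified_ods()` builds long-term, short-term
  and diel-matched surfaces, pairing daytime decisions with daytime history
  and nocturnal decisions with nocturnal history. The diel boundary
  defaults to hours [6, 18), a choice the user should adapt to the study
  system.
* **Time since last visit (TSLV).** `tslv_state()` / `tslv_advance()` /
  `tslv_lookup()` maintain a cell-level map of the most recent visit time.
  Revisitation is counted at the grain of a grid cell (2 km cells are the
  reference grain), never-visited cells report a configurable default of
  365 days — equivalent to assuming they were last visited a year before
  tracking began — and visited cells carry uncapped elapsed time.
  `burn_in_initialize()` sacrifices an initial tracking period to prime the
  map before fitting. With linear plus quadratic TSLV terms, selection can
  peak at an intermediate return time; `tslv_optimum()` returns the vertex
  $-\beta_\text{lin} / (2\beta_\text{quad})$ and `rss_curve()` traces the
  full relative-selection-strength profile.
* **Migration memory.** `min_distance_to_path()` (reported in km in model
  terms) and `directional_bias()` (cosine of the angle between a candidate
  step and the vector to a remembered range centroid, in $[-1, 1]$) encode
  navigation toward a previous year's route and seasonal range. The
  centroid of a range is the arithmetic mean of its locations.

Units matter for interpreting coefficients: TSLV is in days, path distance
in kilometers, the continuous OD covariate is a density in points per
km^2 (the same Gaussian KDE evaluated exactly at candidate endpoints), and
directional bias is dimensionless.

## Fitting

`fit_clogit()` maximizes the conditional-logistic (stratified softmax)
log-likelihood written directly from the model above, with log-sum-exp
stabilization, Newton-Raphson iteration on standardized covariates, and
step halving; the likelihood is concave, so convergence is to the global
maximum on non-degenerate data. The coefficient covariance is the inverse
observed information at the optimum; inference is Wald-based per
coefficient. Perfect separation — a covariate whose used value is always
extreme, sending its coefficient to infinity — is detected as a
standardized coefficient exceeding 10 within-design standard deviations
and reported via the `separation` flag rather than as a converged fit.
Tests cross-check the fitter against an independent implementation
(`survival::coxph` with the exact partial likelihood) and against dense
grid search.

Degenerate inputs are handled explicitly: zero step lengths are replaced
by half the smallest positive step length before kernel fitting (keeping
strata aligned; the count is reported), a diverging turning-angle
concentration is capped at $\kappa = 700$ (the Bessel-overflow guard) with
a warning, terms constant within every stratum are rejected as
inestimable, and an empty OD window is an error rather than a zero
surface, to distinguish "no information" from "zero intensity".

## The simulator and the synthetic scenarios

`simulate_track()` runs the same model forward: at each step it draws
`n_candidates` endpoints from the kernel (default M = 200), weights them
by $e^{\beta_w^\top r + \beta_f^\top f}$ — the kernel factor is embodied
in the proposal — and advances the memory state online. Occurrence memory
at a decision taken at time $t_1$ is built from fixes in $[t_1 - w, t_1)$;
the TSLV map includes the visit at $t_1$, and candidates are evaluated at
their arrival time. The replaying covariate builders
(`add_od_covariate()`, `add_tslv_covariate()`) use exactly the same
conventions, so simulator diagnostics and replayed lookups agree exactly —
a bookkeeping identity the test suite asserts. Candidates falling outside
the domain get zero weight (truncation rather than reflection, which would
distort turning-angle distributions), and fitting-time strata are clipped
with `clip_strata_to_domain()` to match.

Because no forward-simulation protocol is prescribed by the fitting
framework itself, the simulator's conventions (candidate count, update
cadence, boundary truncation) are package decisions; M = 200 was checked
by a doubling test on one-step choice expectations, and a config `stride`
lets the occurrence surface be reused across steps for speed at the cost
of exact replay.

`make_scenario()` generates the four archetypal study designs on seeded
Gaussian-random-field landscapes (256 x 256 cells or smaller, tracks of at
most a few thousand steps, so the whole recovery suite runs in minutes on
one CPU):

| scenario | memory | true familiarity effect |
|---|---|---|
| `bear_like` | TSLV on 2 km cells, default 365 d, 4-h fixes, 3000 steps | quadratic in TSLV, vertex 180 days |
| `hog_like` | 3-day occurrence window, 2-h fixes | density attraction, $\beta_{od} = 1.5$ per km$^{-2}$ |
| `crane_like` | previous season's 95% OD contour | indicator attraction, $\beta = 1$ |
| `deer_like` | previous path + range centroid | $\beta_{dist} = -0.8$/km, $\beta_{dir} = 1.5$ |

The bear vertex of 180 days and the effect sizes are chosen so the
quadratic response is identifiable within a simulated multi-season track;
they are fixtures of the synthetic design, not estimates of any real
population. What passing recovery tests show is that the estimator is
consistent and its intervals calibrated *under the model's own
assumptions* — regular fixes, a known landscape, memory of the assumed
form. They cannot show robustness to the things real telemetry brings:
location error, irregular gaps, unmeasured habitat drivers correlated
with past use, or memory dynamics (decay, valence) outside the covariate
families implemented here.

## The site-fidelity experiment

A long-standing theoretical claim is that preference for familiar
locations is sufficient for stable home ranges to emerge. The package
expresses this as a paired-seed experiment: walkers with never-forget
occurrence memory (window $\infty$, 500 steps) and strong attraction to
familiar space ($\beta_{od} = 4$ on the km$^{-2}$ density scale) versus
the same seeds with no attraction, compared by 95% minimum-convex-polygon
area (`mcp_area()`). Strong attraction is the point of the experiment —
it is the premise of the claim — and under it ranges collapse by orders
of magnitude; weak attraction at these time horizons does not reliably
separate from an unanchored walk, which is itself informative about the
statistical power of fidelity contrasts on short tracks.

## Worked example

```{r, eval = FALSE}
scn <- make_scenario("bear_like", seed = 1)
sim <- simulate_track(scn$config, landscape = scn$landscape,
                      start = scn$start)

strata <- build_strata(sim$track, scn$config$kernel, n_avail = 20,
                       seed = 2) |>
  clip_strata_to_domain(scn$config$gridspec) |>
  add_habitat_covariate(scn$landscape$habitat, outside = 0) |>
  add_tslv_covariate(sim$track, scn$config$gridspec)

fit <- fit_clogit(build_design(strata, terms = c("habitat", "tslv"),
                               quadratic = "tslv"))
tidy(fit, conf.int = TRUE)
tslv_optimum(fit)          # ~180 days
plot_rss_curve(rss_curve(fit, "tslv", 0, 730, conf.level = 0.95),
               xlab = "time since last visit (days)")
```

## Numerical choices and limitations

* Decimal days are the time unit throughout (TSLV is conventionally in
  days); hour-of-day derives from the fractional day, so no timezone
  machinery exists — tracks should be supplied in local time if diel
  stratification matters.
* Turning angles are counterclockwise-positive in $(-\pi, \pi]$; the sign
  convention is arbitrary and documented rather than meaningful.
* Coordinates must be projected planar meters; there is no geographic
  support or resampling to a common fix interval (gaps are kept and
  flagged via `gap_days`, a deliberate user choice).
* Whether TSLV should saturate for long-unvisited cells is genuinely open;
  the package lets visited cells grow unboundedly and reserves the default
  (365 d) for never-visited cells, so the two states remain
  distinguishable.
* Available turning angles are drawn from the fitted von Mises by default;
  a uniform proposal is available by setting $\kappa = 0$ in the
  `kernel_params()` passed to `build_strata()`.
* Out of scope by design: continuous-time OD estimators, hidden-Markov
  hybrid models, jointly estimated mechanistic perception/memory-decay
  parameters, mixed-effects multi-animal fits, and model-selection tables.
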