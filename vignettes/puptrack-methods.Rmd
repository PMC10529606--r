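---
title: "Methods: move persistence and trip analysis for naive grey seal pups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: move persistence and trip analysis for naive grey seal pups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puptrack)
```

## The scientific problem

Newly weaned grey seal (*Halichoerus grypus*) pups leave their natal colony
with no parental guidance and must learn to forage within the lifetime of
their blubber reserves. Fastloc GPS tags deployed on such pups yield
irregular, artifact-laden location streams. `puptrack` implements the full
analysis chain for asking how pup movement behaviour develops over the first
months at sea:

1. quality control of the raw Fastloc fixes;
2. haulout classification and segmentation of the at-sea record into trips,
   with per-trip metrics;
3. splitting and linear interpolation of tracks onto a regular time grid with
   bathymetric covariate annotation;
4. a move-persistence mixed-effects model relating a continuous behavioural
   index to intrinsic and environmental covariates;
5. linear (mixed) models of trip characteristics ranked by AICc.

A first-class synthetic-data module generates bathymetry, cohorts, latent
tracks and tag streams with known ground truth, so every stage is testable at
desk scale without field data.

## The move-persistence model

Let $d_t \in \mathbb{R}^2$ be the displacement (km, local planar coordinates)
between consecutive regular locations of one track. The process is a
first-difference correlated random walk,

$$ d_t = \gamma_t\, d_{t-1} + \varepsilon_t, \qquad
   \varepsilon_t \sim N\!\big(0,\ \mathrm{diag}(\sigma_x^2, \sigma_y^2)\big), $$

where $\gamma_t \in (0,1)$ is the *move persistence*: the autocorrelation in
speed and direction of successive displacements. Values above 0.70 are read
as directed travel, below 0.30 as area-restricted search (a proxy for
foraging), with strict inequalities at both thresholds. Persistence is linked
to covariates through

$$ \operatorname{logit}(\gamma_t) = x_t^\top \beta + b_i, \qquad
   b_i \sim N(0, \sigma_b^2), $$

with a random intercept $b_i$ per animal. The covariate vector holds sex,
weaning mass (kg) and length (cm), post-weaning duration (d), week at sea,
distance to the 0 m isobath (km) and ln water-column depth (m), all on their
natural scales.

The marginal likelihood integrates over each $b_i$ by the Laplace method: an
inner Newton optimization of the scalar intercept per animal (analytic first
and second derivatives) plus the usual log-determinant correction. When
$\sigma_b < 10^{-8}$ the code short-circuits to the conditional likelihood at
$b=0$, the exact limit. The outer optimization is two-stage — a
derivative-free Nelder–Mead pass to generate initial values, then quasi-Newton
refinement with `nlminb` — with covariate columns standardized internally for
conditioning and estimates mapped back to natural scale. Standard errors come
from the inverse observed information (Wald inference, matching the reported
per-coefficient p-values in this literature). The test suite verifies the
Laplace marginal against an independent adaptive Gauss–Hermite quadrature
oracle (21 nodes): agreement is well under $10^{-3}$ log-likelihood units for
random-effect scales up to about 0.15, degrading smoothly (the error is higher
order in $\sigma_b$) to a few $10^{-3}$ at $\sigma_b = 0.25$.

Bookkeeping choices that matter for comparability:

* likelihood-contributing steps are those with a predecessor displacement in
  the same track (a track of $m$ regular points contributes $m-2$ steps); no
  information crosses track boundaries;
* covariates are aligned at each step's destination time;
* $n$ in $\mathrm{AICc} = -2\mathrm{LL} + 2k + 2k(k+1)/(n-k-1)$ is the number
  of contributing steps;
* $k$ counts the fixed effects, $\sigma_b$, and the two innovation sds. Note
  that the R package this model family comes from reports two more parameters
  per model (it carries an unstructured innovation covariance); our innovation
  covariance is diagonal, the simplest form consistent with the model
  description, with a correlation parameter left as an extension point.
* One-step-ahead residuals are plug-in: $(d_t - \hat\gamma_t d_{t-1}) /
  \hat\sigma$ per axis with $\hat\gamma_t$ using the inner modes $\hat b_i$.

## Quality control and trips

The three Fastloc filters run in a fixed order: remove fixes computed from
fewer than 5 satellites; remove residual values strictly greater than 30
(exactly 30 is kept); then a single forward speed sweep that removes any fix
implying more than 10 km/h from the last *retained* fix (great-circle
distance, spherical radius 6371 km). The sweep is simple and auditable; the
suite checks it against a brute-force subset oracle (the kept set is feasible
and maximal). Each removed fix carries exactly the first failing filter as
its reason, so the audit counts decompose the removals.

A fix is hauled out when (i) the tag's wet/dry logic said so, or (ii) the
water column is at most 5 m deep (nearest-cell lookup, depth = −elevation),
or (iii) it lies within 10 km of the colony axis — a 43 km polyline rather
than a point, because a centre-point radius would misclassify the island's
ends. Maximal runs of at-sea fixes bounded by haulouts become trips when
their span strictly exceeds 24 h; a run cut off by the end of transmission is
an incomplete trip and is excluded from trip-characteristic analyses. Trip
metrics are cumulative great-circle distance, duration in days, their ratio
as mean speed, and the haulout duration to the next trip's first at-sea fix.
Types are A (colony to colony), B (exactly one endpoint at the colony) and C
(neither). Trip boundary timestamps are the first/last at-sea fixes, so
durations are lower bounds; weeks at sea count from 1 at the animal's first
at-sea fix, `floor(days/7) + 1`.

## Regularization

Tracks split at every haulout bout and at transmission gaps strictly longer
than 48 h; segments with fewer than 50 fixes are dropped. Longitude and
latitude are interpolated linearly in time on a grid that starts at the first
fix and steps exactly $\Delta$ hours, never extrapolating. The default
$\Delta$ is 6 h; `timestep_diagnostics()` fits the intercept-only persistence
model at 3, 4, 6 and 8 h and reports the intercept standard error, mean
persistence and residual lag-1 autocorrelation per step, but selection is
left to the user — shorter steps interpolate sparse data too aggressively and
show residual autocorrelation. Interpolated locations at or above sea level
take a depth of 1 m so the ln transform is defined. Distance to shore is the
great-circle distance to the nearest 0 m-isobath cell of the same bathymetry
grid used everywhere else, so synthetic and real runs share one code path.

## Trip-characteristic models

Trip frequency (complete trips per deployment day, one row per animal) is
modelled by plain linear models — with one observation per animal a random
intercept is not identifiable, and the published degrees of freedom confirm
plain fits. Trip distance, duration and haulout duration (one row per trip,
ln-transformed) carry an animal random intercept via `lme4`, always by
maximum likelihood so that AICc and likelihood-ratio comparisons across
fixed-effect structures are valid. Marginal and conditional $R^2$ use the
variance-partition formulas
$R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_u + \sigma^2_e)$ and
$R^2_c = (\sigma^2_f + \sigma^2_u) / (\sigma^2_f + \sigma^2_u + \sigma^2_e)$.
Candidate sets are exactly the printed formula lists of the study's four
ranking tables (`trip_candidate_sets()`); boundary fits (zero random-intercept
variance) are flagged singular rather than dropped.

## What the synthetic world emulates — and what it does not

`make_bathymetry()` builds an ETOPO1-style elevation grid: a low sandbar
island, a shallow shelf (default 100 m) carrying banks (30–60 m) and basins
(200–300 m), and an abyssal ramp to at least 1000 m beyond a configurable
shelf-break radius. The island's minor axis is widened to at least one grid
cell so the coastline is resolved at any resolution.

`simulate_track()` runs the persistence process forward at the tag's 15-min
attempt interval, with haulout windows that pin the animal to the nearest
shore cell (depth ≤ 5 m). Scheduled at-sea bouts are lognormal with mean
15.9 d (sd 16.6 d) and haulouts lognormal with mean 33.6 h (sd 29 h), the
study cohort's reported moments; post-weaning durations are a truncated
normal (mean 21 d, sd 6 d, minimum 1 d), and weaning mass/length a bivariate
normal (55 ± 5.5 kg, 112 ± 3 cm, correlation 0.55). The generative
coefficients and the per-axis innovation sd (4 km) are interpreted at the
model's 6 h reference step; when the path is simulated at the tag's 15-min
resolution the recursion uses the time-rescaled persistence
$\gamma^{\Delta t / 6\mathrm{h}}$ with the innovation sd that keeps the
stationary velocity unchanged (the discretization of the corresponding
continuous-time process). This preserves the 6 h autocorrelation structure
that the fitted model sees after interpolation and yields mean horizontal
speeds near the reported 1.7 km/h. `emulate_tag()` thins attempts by a Bernoulli surfacing
probability (default 0.6, tuned only to reproduce the reported inter-fix
spacing quantiles — the true surfacing process is not described), draws
satellite counts over 4–11 (mass 0.08 at 4) and exponential residuals (mean
8), suppresses fixes inside haulout windows after the tag's 20-min dry-entry
criterion, and injects position outliers whose displacement is scaled to the
gap since the last good fix so they always exceed the 10 km/h QC threshold.

Two deliberate departures from the pure process keep the artifacts realistic:
near the end of an at-sea bout the innovation is blended toward the upcoming
haulout site (so haulout entry is continuous rather than a teleport that the
speed filter would flag), and for the first 18 h after a haulout the animal
is pushed offshore along a fixed outbound heading (real pups leave in
directed travel; a purely diffusive walk lingers inside the colony radius and
the shallow nearshore zone). Both distort the generative model
near haulouts, which is why parameter-recovery studies use
`simulate_model_data()` instead: it draws displacement series *exactly* from
the process at the model's own time step, emits the covariate values that
generated each step, and contains tracks only by reflection at the grid edge.
Recovery runs use a wide grid (lon −64.5..−55, lat 41..47) so that
reflections are negligible (<2% of locations near an edge at study scale).

What passing these tests shows is that the estimator recovers the model it
assumes under realistic effect sizes, sample sizes and tag artifacts. It does
not show that real pup movement follows a first-difference CRW, that Fastloc
errors are absent after filtering, or that the environmental fields of the
real shelf behave like the synthetic one (no tides, currents, or prey fields
are simulated; dive behaviour is out of scope).

## Numerical choices and problem sizes

* Local planar coordinates: equirectangular with cos-latitude scaling, per
  track about its centroid for modelling (keeps innovations near-isotropic at
  shelf latitudes), about the island for simulation.
* Moment-based starting values: the pooled displacement autocorrelation
  (clamped to (0.05, 0.95)) seeds the logit intercept; residual sds seed the
  innovation scales; $\sigma_b$ starts at 0.25.
* Inner Newton: at most 60 iterations, step-halving, gradient tolerance
  $10^{-9}$, with a bracketed fallback if the curvature is non-negative.
* Ties and degenerate inputs: empty streams yield empty outputs with zeroed
  audits; single-fix trips have distance 0 and undefined speed; perfectly
  collinear covariates report infinite VIF with a warning; non-positive
  responses under a ln transform are an error listing the rows.
* Test and validation sizes were chosen to keep a desk-scale run fast while
  preserving the study's structure: oracle checks use 2 animals × 30 steps,
  recovery tests 12 animals × 150 steps, and the acceptance script refits the
  full study scale (22 animals × 260 six-hour steps, ~5,700 likelihood steps)
  with four replicates plus a reduced leave-one-out pass (10 animals).

## Known limitations

* Wald intervals for between-animal covariates (sex, mass, length,
  post-weaning duration) are anti-conservative at 22 animals because the ML
  estimate of $\sigma_b$ is biased low; a REML-like correction is not
  implemented. Week and distance-to-shore estimates trade off against each
  other in cohorts whose position drifts offshore over time (collinearity of
  secular trends), so the week coefficient is recovered with the right sign
  but attenuated magnitude at realistic effect sizes.
* The innovation covariance is diagonal; a cross-axis correlation parameter
  is an extension point.
* Random slopes and fixed-effect interactions are intentionally not supported
  in the persistence model, matching the scope of the published analysis.
* The speed filter is a forward sweep, not a root-mean-square multi-pass
  filter; the strategy is configurable in principle but only the sweep is
  implemented.
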