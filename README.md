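# puptrack

Movement ontogeny of naive grey seal pups from Fastloc GPS telemetry.

Newly weaned grey seal (*Halichoerus grypus*) pups leave their natal colony
with no parental guidance and must learn to forage before their blubber
reserves run out. Biologists study this transition by tagging pups with
Fastloc GPS transmitters and asking how movement behaviour — trip structure
and a continuous behavioural index called *move persistence* — develops over
the first months at sea and how it relates to sex, weaning size, time, and
habitat. `puptrack` implements that analysis chain end to end, for telemetry
analysts working with central-place pinniped data:

* **Quality control** of raw Fastloc fixes: remove fixes with fewer than 5
  satellites, Fastloc residuals above 30, then a forward 10 km/h speed sweep,
  with a per-filter audit.
* **Trips**: haulout classification (tag wet/dry flag, water column ≤ 5 m, or
  within 10 km of the colony axis), segmentation into trips (> 24 h at sea),
  trip metrics (duration, cumulative great-circle distance, mean speed,
  subsequent haulout duration) and types (colony return / mixed / between
  other haulouts).
* **Regularization**: track splitting at haulouts and > 48 h gaps, linear
  interpolation to a regular time step (default 6 h), and annotation with
  water depth, distance to the 0 m isobath, and week at sea.
* **Move-persistence mixed-effects model**: for per-step displacements
  `d_t`,

  ```
  d_t = gamma_t * d_{t-1} + eps_t,          eps_t ~ N(0, diag(sigma_x^2, sigma_y^2))
  logit(gamma_t) = x_t' beta + b_i,         b_i ~ N(0, sigma_b^2)
  ```

  fitted by maximum likelihood with a Laplace-approximated marginal over the
  per-animal intercepts `b_i`, AICc model selection with Akaike weights,
  Wald inference, one-step-ahead residuals, VIFs, and leave-one-out
  cross-validation of coefficient stability. `gamma_t > 0.70` is read as
  directed travel, `gamma_t < 0.30` as area-restricted search.
* **Trip-characteristic models**: linear models of trip frequency and
  animal-random-intercept mixed models (lme4, ML) of ln trip distance,
  duration and haulout duration, ranked by AICc with likelihood-ratio
  confirmation.
* **Synthetic world**: a shelf-like bathymetry (island, banks, basins, shelf
  break), simulated cohorts, latent tracks with known persistence dynamics,
  and an emulated tag (15-min attempts, surfacing thinning, haulout
  suppression, satellite counts, residuals, injected outliers) so the whole
  pipeline is testable with known ground truth.

## Worked example

Simulate a 4-pup scenario, run QC, build one animal's trips, and fit
persistence models to the whole cohort:

```r
library(puptrack)
library(dplyr)

scen <- simulate_scenario(n_pups = 4, deployment_days = 60, seed = 7)
qc <- filter_fixes(scen$fixes)
qc$report
#>   n_input n_removed_satellites n_removed_residual n_removed_speed n_kept
#> 1   13249                 1044                284             125  11796

a <- scen$pups$id[2]
stream <- qc$kept[qc$kept$id == a, ]
calls <- classify_haulout(stream, scen$bathy, scen$colony)
trip_summaries(stream, calls, scen$colony)$trips
#>   trip_no complete       type duration_d distance_km mean_speed_kmh haulout_duration_h week_at_end
#> 1       1     TRUE          A      13.98         357           1.07               57.0           2
#> 2       2     TRUE          A      10.55         349           1.38               43.2           4
#> 3       3     TRUE          A       2.66         105           1.65               60.2           5
#> 4       4     TRUE          A      16.43         441           1.12               97.2           8
#> 5       5    FALSE incomplete       5.31         141           1.10                 NA           9
```

The QC audit says 1,453 of 13,249 raw fixes fail the satellite/residual/speed
filters. This pup then makes four complete return trips to the colony
(type A) of 2.7–16.4 days and 105–441 km at 1.1–1.7 km/h, resting ashore
43–97 h between trips; its last trip is cut off by tag failure and excluded
from trip statistics.

```r
shore <- shore_distance_grid(scen$bathy)
tracks <- bind_rows(lapply(scen$pups$id, function(a) {
  s <- qc$kept[qc$kept$id == a, ]
  cl <- classify_haulout(s, scen$bathy, scen$colony)
  ts <- trip_summaries(s, cl, scen$colony)
  if (is.na(ts$first_at_sea)) return(NULL)
  regularize_animal(s, cl, scen$bathy, scen$pups[scen$pups$id == a, ],
                    ts$first_at_sea, delta_h = 6, shore_grid = shore)
}))
md <- build_model_data(tracks)
rank <- model_select(md, list(~ 1, ~ week + ln_depth, ~ week + dist_shore + ln_depth))
rank
#>                            model df logLik AICc dAICc    weight
#> 1 ~ week + dist_shore + ln_depth  7  -4479 8973  0.00 1.000e+00
#> 2                            ~ 1  4  -4495 8999 26.14 2.107e-06
#> 3              ~ week + ln_depth  6  -4495 9002 28.90 5.289e-07

attr(rank, "fits")[[rank$model[1]]]
#> Move-persistence mixed-effects model (Laplace ML)
#> formula: ~ week + dist_shore + ln_depth
#>         term  estimate       se        z         p
#>  (Intercept)  0.409651 2.139416  0.19148 8.482e-01
#>         week  0.001966 0.047410  0.04147 9.669e-01
#>   dist_shore -0.010302 0.001957 -5.26317 1.416e-07
#>     ln_depth  0.394164 0.484264  0.81394 4.157e-01
#> sigma_b = 0.3132 ; sigma_step = 3.274, 3.339 km
#> logLik = -4479.29  k = 7  n = 856  AICc = 8972.72
```

The environmental model is decisively preferred over the null (ΔAICc 26):
pups farther from shore show lower move persistence (negative `dist_shore`
coefficient, here the dominant effect at this small cohort size).
`classify_gamma()` on the fitted series labels 574 of 856 six-hour steps as
directed travel and none as area-restricted search — the exploratory,
travel-dominated pattern expected of naive pups.

`run_pipeline()` wraps the whole sequence (simulation or CSV/ESRI-ASCII
inputs → QC → trips → regularization → persistence and trip models → CSV/JSON
report bundle with a config-hash manifest); `inst/cli/puptrack.R` is a thin
command-line wrapper over it.

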