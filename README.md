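# sealwinter

Analysis tools for the winter migration of adult northern fur seals
(*Callorhinus ursinus*) tracked by satellite-linked tags. Adult males and
females of this species are strongly size-dimorphic and winter in different
regions of the North Pacific and Bering Sea; the open question is how
physiology and the physical environment — light from the sun and the moon,
wind, season, the surface mixed layer and the ecosystem occupied — shape the
horizontal movement and diving of each sex. `sealwinter` implements the
full analysis chain needed to ask that question of biologging data, and a
synthetic-data generator with planted ground truth so every stage can be
tested end to end without access to field data.

## What the package computes

**Movement.** `fit_sssm()` regularises irregular, error-prone Argos fixes
onto a 6-h UTC grid with a Bayesian switching state-space model. The
process model is a first-difference correlated random walk whose move
persistence switches with a 2-state Markov chain,

d_t = gamma_{s_t} d_{t-1} + e_t,  e_t ~ N(0, sigma^2 I),  s_t in {1, 2},

with state 1 (transient travel) identified by high persistence and state 2
(area-restricted residency) by low persistence; fixes observe the linearly
interpolated path with fixed Gaussian error per Argos location class
(3, 2, 1, 0, A, B). Estimation is Metropolis-within-Gibbs (compiled in
C++); the behavioural index `b` in [0, 1] is the posterior mean of the
resident-state indicator, and `transform_state()` applies the clamped logit
used for downstream regression.

**Mixed layer.** `detect_mld()` finds the mixed-layer depth of a sparse
(<= 17-point) animal-borne CTD cast by a seasonal density-difference
criterion: scanning sample pairs below 10 m for the first density step
exceeding 10% of Delta-sigma_t, where Delta-sigma_t is the density increase
from cooling the reference sample by a season-specific Delta-T (1.0 C
winter, 0.8 C spring/fall, 0.2 C summer), then interpolating the depth at
which sigma_t exceeds the reference by Delta-sigma_t. A 10-m-referenced
secondary method covers unstable or weakly stratified casts; spike QC and
cast-to-block averaging/interpolation (`quality_control()`,
`align_mld_to_blocks()`) complete the module. `sigma_t()` is the EOS-80
surface equation of state.

**Dive records.** `clean_records()`, `histogram_mean()` and
`summarize_dive_blocks()` process both tag families into a common 6-h
representation: 14-bin depth/duration histograms (SPLASH) and onboard
summary statistics (SRDL), with duplicate removal, the >6 m depth and
>15 s duration filters, and a count-weighted bin-midpoint mean.

**Covariates and habitat.** `proportion_daylight()` (NOAA solar-position
equations, nautical twilight at −12°), `lunar_fraction()`
(truncated-series lunar ephemeris, M = (1 − cos ψ)/2), `wind_at()`
(nearest-cell alignment to 6-hourly gridded winds; WS = sqrt(u² + v²)),
`season_days()` (days since 1 October), `assign_lme()` (Large Marine
Ecosystem polygons), `stormy_proportion()` (share of days with wind speed
over 11 m s⁻¹) and `eddy_edge_distance()` (great-circle distance to the
nearest eddy edge, negative inside).

**Inference.** `fit_lmm()` fits the behavioural responses (logit state,
log mean depth, log dive count) by maximum likelihood with a per-seal
random intercept and AR(1) within-seal errors (via `nlme`), Wald t-tests
with containment df, and `aic_rank()` compares fixed-effect sets by AIC
(K = fixed effects + 3 variance/correlation parameters);
`mass_regression()` handles the per-animal mass-vs-dive-metric fits.

**Synthetic data and pipeline.** `sim_config()` plus
`simulate_track()/simulate_dive_blocks()/simulate_ctd_profiles()/
simulate_wind_field()/simulate_eddies()` generate every input with planted
truth; `run_pipeline()` chains all stages and `tracking_summary()`
computes the cohort deployment/coverage summaries from the packaged
deployment table.

## Worked example

```r
library(sealwinter)

cfg <- sim_config(n_seals = 1, n_blocks = 200, seed = 4)   # ~50 days
sim <- simulate_track(cfg, id = "sim01")
fit <- fit_sssm(sim$fixes, iters = 4000, burn = 2000, thin = 2,
                chains = 2, seed = 9)
fit
#> Switching state-space model fit: sim01
#>   370 fixes -> 200 six-hour blocks (2009-11-01 .. 2009-12-20)
#>   mean behavioural index b = 0.58 (0 transient, 1 resident)
#>   gamma: transient 0.84, resident 0.15; process SD 3.04 km/6h
```

The planted values were gamma = (0.85, 0.20) and process SD 3 km, so the
posterior means (0.84, 0.15, 3.04) recover the generating movement process;
`summary(fit)` adds credible intervals and split-chain R-hat, and
`fit$track` holds the 6-h positions with `b` per block.

```r
cast <- simulate_ctd_profiles(40, as.POSIXct("2010-01-10 06:00", tz = "UTC"),
                              noise_sd = 0.01, seed = 2)[[1]]
detect_mld(cast)
#> MLD result [seal1]: found_primary, 46.5 m (dT = 1.0 C, winter)
```

The 40-m planted layer is recovered within the ~15-m sample spacing of the
17-point cast.

```r
ts <- tracking_summary(read_deployments())
ts$cohort
#> $max_departures_in_window       10
#> $longest_migration_female       139
#> $longest_migration_male         194.9
#> $min_transmission_span          41
#> $mass_ratio_max_male_min_female 8.21
```

From the packaged deployment table: ten of the fifteen animals departed
within one 10-day window, the longest tracked migrations were 139 d
(female) and 194.9 d (male), every transmitter lasted more than 40 d, and
the largest male outweighed the smallest female 8.2-fold.

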