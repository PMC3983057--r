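---
title: "Models and methods in sealwinter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in sealwinter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sealwinter` provides, as tested and reusable components, the analysis
chain for a dual-sex fur-seal winter biologging study: state-space
regularisation of Argos tracks with a behavioural-state index, mixed-layer
depth (MLD) detection from sparse animal-borne CTD casts, construction of
solar/lunar/wind/season covariates, processing of 6-h dive summaries from
two tag families, habitat and storm/eddy metrics, and mixed-effects
inference. This vignette records the models, their assumptions, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## The switching state-space movement model

Argos fixes arrive at irregular times with class-dependent positional
error. `fit_sssm()` estimates positions $x_t$ on the regular 6-h UTC grid
(block starts 00/06/12/18) and a behavioural index per block. The process
model is a first-difference correlated random walk with a switching
persistence coefficient,
$$ d_t = x_{t+1} - x_t, \qquad
   d_t \mid d_{t-1}, s_t \sim N(\gamma_{s_t}\, d_{t-1},\ \sigma^2 I_2), $$
with $s_t \in \{1, 2\}$ a first-order Markov chain. State 1 is transient
(fast, directed travel: high persistence) and state 2 resident
(area-restricted movement: low persistence). The first displacement $d_1$
is given a diffuse $N(0, 50^2\,\mathrm{km}^2)$ prior. A fix at time $\tau$
inside block interval $[t, t+1]$ observes the linearly interpolated path,
$$ y_i \sim N\big((1-w)x_t + w\,x_{t+1},\ \sigma_{c_i}^2 I_2\big),
   \qquad w = (\tau - t)/6\,\mathrm{h}, $$
with a fixed, configurable error SD per Argos class (defaults 0.25, 0.5,
1.5, 4, 6, 10 km for classes 3, 2, 1, 0, A, B; per-class magnitudes vary
by deployment, so these are conventional telemetry values, not asserted
ones). Coordinates are projected onto a local tangent
plane (km) at the circular-mean fix location and back-projected for
output; at track scales of a few thousand km the equirectangular
projection error is far below the Argos error.

Sampling is Metropolis-within-Gibbs, compiled in C++: adaptive random-walk
Metropolis for each $x_t$ (per-block proposal scales tuned toward a 35%
acceptance rate during burn-in only, so the post-burn-in chain is a valid
fixed-kernel sampler), and conjugate Gibbs updates for the states
(2-point conditionals), the persistence parameters (truncated normal), the
process variance (inverse gamma, prior IG(2, 1) in km$^2$) and the
transition rows (Beta(1, 1)). Two labelling conventions fit the same
likelihood, so the states are identified by separated supports:
$\gamma_1 \in (0.5, 1]$ and $\gamma_2 \in [0, 0.5)$ (`gamma_split`,
default 0.5). A plain ordering constraint is not enough — on a track that
never leaves the transient state, the resident persistence is free to
drift up against the transient value and the state labels mix arbitrarily;
the separated supports pin "resident" to genuinely low persistence, which
is what the index is meant to measure. Tracks whose transient behaviour has
persistence below 0.5 would need a lower split; the parameter is exposed.

The behavioural index $b_t$ is the posterior mean of the resident-state
indicator, so $b = 0$ is pure transit and $b = 1$ pure residency. For
regression use, `transform_state()` maps $b$ through a logit after moving
exact 0s and 1s inward by $10^{-4}$ — only the exact endpoints are
touched.

Defaults are 2 chains of 10,000 iterations (5,000 burn-in, thinning 5);
the closed-loop tests use shorter chains (600–4,000 iterations) because
the synthetic posteriors they examine are tight; all lengths are
arguments. Determinism: all randomness flows through R's RNG, so a seed
fixes the fit bit-for-bit, and input fix rows are sorted internally so row
order is irrelevant.

## Mixed-layer depth from sparse casts

Seawater density is computed as $\sigma_t$ = EOS-80 density at surface
pressure minus 1000 kg m$^{-3}$ (`sigma_t()`, verified against the UNESCO
check values). Casts are shallow, so the surface form suffices and no
potential-density correction is applied.

The detector (`detect_mld()`) uses a seasonal density-difference
criterion. The density increment is
$\Delta\sigma_t = \sigma_t(T_n - \Delta T, S_n) - \sigma_t(T_n, S_n)$ — the
density increase from cooling the reference sample by the
season-prescribed $\Delta T$: 1.0 °C in January–March, 0.8 °C in
April–June, 0.2 °C in July–September, 0.8 °C in October–December. The
primary method scans sample pairs from 10 m for the first pair whose
density step exceeds $0.1\,\Delta\sigma_t$ (computed per pair at the upper
sample, rather than once per cast); that upper sample sets
the reference density, and the MLD is the first depth at which the
piecewise-linear $\sigma_t$ profile exceeds reference $+\ \Delta\sigma_t$,
found by linear interpolation. The secondary method re-references to the
interpolated 10-m density; it runs when the water column above 10 m is
unstable (any density decrease with depth exceeding 0.02 kg m$^{-3}$ —
"unstable" needs a tolerance to be operational, so the default is explicit
and configurable), when density rises
$2\Delta\sigma_t$ above the 10-m reference before the pair criterion
fires, or when the primary reference yields no exceedance. Casts not
reaching 10 m, and casts on which neither method finds an exceedance, are
reported as `shallower_than_max_dive`; a found MLD is always in
[10 m, cast bottom] by construction. The detector is tested for exact
agreement (status and depth within 0.05 m) with an independent dense-scan
re-implementation on 1,000 random synthetic casts.

Quality control (`quality_control()`) removes density-spike samples before
detection. An interior sample is a spike when both adjacent $\sigma_t$
jumps reverse sign and exceed min(10 × the cast's median absolute jump,
1 kg m$^{-3}$); the sign-reversal requirement protects genuine pycnoclines,
which are monotone. End samples cannot be screened by sign reversal, so
they are removed only on the absolute criterion. A purely median-relative
rule was rejected because it cannot flag a cast in which every jump is a
spike (the median scales with the spikes), and, with a floored median,
misclassifies the pycnocline of a noiseless cast as an endpoint spike.
Casts reduced below two samples, or still containing point-to-point jumps
above 5 kg m$^{-3}$ after cleaning, are rejected.

`align_mld_to_blocks()` averages found MLDs within each 6-h block and
optionally fills interior gaps by linear interpolation. Gap-filling of
this kind is often left to expert judgement; here it is an auditable rule
with two thresholds — gap at most 2 blocks (12 h) and flanking MLDs
within 15 m of each other — chosen so that interpolation only bridges
short, quiet stretches and never invents structure across fronts.

## Covariates

**Proportion daylight (D).** Solar elevation from the NOAA
solar-calculator equations (Julian-century mean elements, equation of
centre, apparent longitude, mean obliquity, equation of time), without
refraction — irrelevant at the −12° nautical-twilight threshold. D is the
fraction of one-minute samples across the 6-h block with elevation
≥ −12°, evaluated at the animal's block-midpoint position held fixed.
Sampling, rather than solving for dawn/dusk crossings, stays well defined
at high latitudes where a block may contain zero or two crossings. The
implementation is cross-checked against an independently coded PSA solar
algorithm (elevations within 0.3°; block fractions within one minute).
Note that by the nautical definition there is no polar night at 57–75°N:
even at the winter solstice the noon sun at 75°N is only 8.4° below the
horizon. True D = 0 days require latitudes above ≈78.6°N.

**Lunar fraction (M).** Geocentric illuminated disk fraction
$(1 - \cos\psi)/2$ with $\psi$ the Moon–Sun elongation from a
truncated-series lunar ephemeris (mean longitude plus the six largest
longitude terms and three latitude terms) and the same solar longitude
used for D. Accuracy is a few thousandths of the disk fraction, verified
against a packaged table of published new/full/quarter instants. M is
evaluated at the block midpoint and is location-independent, matching the
use of a date-level almanac table.

**Wind (WS, direction).** 6-hourly u/v fields on a 2.5° grid are aligned
nearest-neighbour in space and exactly in time (the 6-h blocks coincide
with the synoptic hours), then converted to speed $\sqrt{u^2+v^2}$ and
direction-toward (atan2(u, v), clockwise from north); calm cells report a
missing direction. No NetCDF reader exists in the supported R stack, so
grids are serialised in a self-describing plain-text format
(`write_wind_grid()`), which also keeps all fixtures text-only.

**Season (S).** Fractional days since 1 October 00:00 UTC of the
deployment season (inferred as the most recent 1 October unless given).

**Habitat.** Six Large Marine Ecosystem regions (BS, BB, AS, NP, GA, CC)
ship as simplified synthetic GeoJSON polygons
(`lme_regions_synthetic.geojson`): no authoritative region file exists to
package, so these rectangles/along-isobath approximations reproduce the
qualitative geography (including the shelf/basin split near the
1000-m isobath) but are not the original analysis polygons. Containment is
ray casting with an explicit convention — boundary points count as inside,
first-listed region wins ties. Storminess is the per-cell share of UTC
calendar days in 1 November–31 March with any synoptic wind speed above
11 m s$^{-1}$ (several daily reductions are defensible;
any-exceedance is the documented choice here). Eddy proximity is the
haversine distance (sphere radius 6,371 km — eddy radii are approximate,
so ellipsoidal precision is unwarranted) to the nearest eddy centre minus
its radius; negative means inside.

## Dive-record processing

SPLASH tags store 6-h histograms in 14 predefined depth bins (upper limits
2, 4, 6, 10, 20, 34, 50, 74, 100, 124, 150, 174, 200 m and an open top
bin) and duration bins; SRDL tags store onboard summary statistics of
dives deeper than 6 m. The printed duration-limit list contains 13 values
but is stated to have 14 bins; the missing 270 s limit, where the list's
otherwise regular 30 s spacing would place it, is included to complete the
layout (limits are arguments throughout). Bins are half-open `(lower,
upper]` intervals — a dive exactly at a limit falls in that limit's bin.
Cleaning removes duplicate records per (animal, block), zeroes depth bins
with upper edge ≤ 6 m (aligning the two tag families' dive definitions; the
bin granularity cannot split a bin, so the >6 m filter acts on whole bins)
and the shortest duration bin, and rejects records not on a 6-h boundary.
The histogram mean weights each bin's midpoint by its count; the open top
bin is represented by its lower edge plus half the width of the last
closed bin (213 m, 375 s), configurable, as any open-bin
representative value is a convention. An empty histogram has no mean and reports NA
rather than zero.

## Mixed-effects inference

The behavioural responses — logit state, log mean depth, log dive count
(zero-dive blocks are excluded before logging) — are modelled with fixed
effects from {WS, sex, S, D, M, LME, MLD} and interactions, a per-animal
random intercept, and AR(1) errors within animal:
$$ V_\text{animal} = \sigma_b^2 J + \sigma^2 R(\phi), \qquad
   R_{jk} = \phi^{|i_j - i_k|}, $$
with $i$ the 6-h block index, so gaps decay as $\phi^{\text{lag}}$.
Estimation is maximum likelihood, not REML, because AIC values are
compared across fixed-effect sets; the fitting engine is `nlme::lme`
(nlminb optimiser, with an optim retry on error), and the test suite
verifies the reported log-likelihood against a hand-coded dense
multivariate-normal evaluation to 10$^{-8}$. Wald t-tests use containment
(within-group) degrees of freedom. `aic_rank()` sorts by
AIC $= -2\ell + 2K$ with $K$ = number of fixed effects + 3
(intercept SD, $\phi$, residual SD), counting every estimated parameter
of the marginal model.

Calibration measured by the acceptance checks: under a correctly modelled
AR(1) null the Wald test's size is close to nominal (the criterion band is
0.03–0.07 at $\alpha$ = 0.05 over 500 simulations with 10 animals × 60
blocks). Joint 2-SE coverage of both fixed effects at 20 animals × 200
blocks is ≈0.9: ML variance components and finite-sample Wald intervals
are mildly anticonservative, which is inherent to the prescribed
estimator rather than an implementation artefact (the likelihood itself is
oracle-verified).

## The synthetic-data generator

The generator emulates the study's data streams under the stated
conditions: deployments from St. Paul Island (57.2°N, 172.2°W) starting
late October; 6-h blocks (~100 days per animal by default, 400 blocks); a
two-state movement process with persistence 0.85 (transient) and 0.20
(resident), 3 km process SD per 6 h, and a persistent transition matrix
(0.95 diagonal); Argos fixes at 8/day with the class-specific error SDs
above; dive depths log-normal about a log-linear predictor in D, M and MLD
with coefficients (3.0, 0.3, 0.2, 0.01) — magnitudes comparable to the
fitted study models — and Poisson dive counts; two-layer CTD casts with up
to 17 samples (uniform above the planted MLD, a 30-m pycnocline below);
AR(1) synoptic winds with storm days at frequency 0.15 adding 14 m s$^{-1}$;
and weekly uniform eddy catalogs with 40–150 km radii. Turning is von
Mises per state (`turn_kappa`); the default is no turning, which makes the
generator exactly the model family the fitter assumes — the recovery tests
are deliberately matched generative tests. Every generator is seeded and
bit-reproducible, and all outputs serialise to delimited text with a JSON
ground-truth sidecar.

What passing these tests shows: the samplers, detectors and fitters
recover what they claim to estimate when their assumptions hold, at
realistic noise levels and sample sizes. What they do not show: robustness
to heavy-tailed Argos errors (a Gaussian-only contract; a heavier-tailed
option exists in the generator design space but the fitter assumes
Gaussian), to prey-field or bathymetric structure in dive depths, to
thermal-lag or salinity-drift artefacts in the CTD casts, or to
mis-specified movement dynamics (e.g. strong turning in the resident
state biases the resident persistence toward its effective, turn-shrunk
value).

## Problem sizes and runtime

The default test and acceptance runs use: 1,000 random casts for the MLD
oracle equivalence; 20 replicates of 400-block tracks (2 chains × 3,000
iterations) for movement recovery; 20 replicates of 20 animals × 200
blocks for mixed-model recovery; 500 null simulations of 10 animals × 60
blocks for test size; and the packaged deployment/dive tables for the
cohort summaries. The full suite runs in about a minute on one CPU, the
acceptance script likewise; these sizes were chosen to make Monte Carlo
error small relative to each criterion's margin.

## Known limitations

- The movement model is discrete-time with exactly two states; behavioural
  nuance beyond transit/residency loads onto the index's intermediate
  values.
- Argos error SDs are fixed inputs, not estimated; misstating them scales
  position credible intervals accordingly.
- The LME polygons are qualitative stand-ins; analyses of real tracks
  should substitute the user's own region file via `read_lme_regions()`.
- Lunar fraction is geocentric (no topocentric or altitude weighting), and
  D/M are evaluated at block midpoints; both match the upstream
  convention but smooth over within-block variation.
- `histogram_mean()`'s open-bin representative value is a convention;
  deep-diving records with mass in the open bin carry the corresponding
  uncertainty.
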