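---
title: "Modelling reef susceptibility to coral rubble accumulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reef susceptibility to coral rubble accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefrubble)
```

## The problem

Disturbances such as cyclones and mass bleaching convert living coral into
loose rubble. Where rubble stays mobile it abrades and smothers recruits,
and reefs can fail to recover for decades. Whether rubble persists in a
location is governed largely by the local bathymetry: rubble collects in
depressions and on flat sections of the fore-reef slope, rolls off steep
structure, and cannot sit on local topographic highs. `reefrubble`
implements a transect-based screening model of this process: given depth
profiles sampled down reef slopes, it flags every 10-m point where rubble
could accumulate, and aggregates the flags into reef- and region-scale
susceptibility metrics, a parameter sensitivity analysis, and a
depth-by-aspect regression. The model is morphological only — it estimates
*where rubble could collect*, not how much rubble forms, moves, or
stabilises; hydrodynamic forcing is deliberately outside its scope.

Depths throughout the package are **positive-down metres**: "depth 12" is
12 m below mean sea level. External rasters conventionally store negative
elevations; `read_bathymetry_asc()` negates at the I/O boundary so that the
decision rules below never need double negatives.

## The decision tree

Each profile point (the *focal point*) is judged inside a moving window
that extends `moving_window_m` to both sides along the transect (50 m = 5
samples each side at base case). With `range` the max minus min depth over
the window including the focal point:

1. **Roll-off exclusion.** If `range >= roll_depth_range_m` (base 5 m) the
   focal point is on or near steep structure and rubble rolls away: no
   rubble. The boundary value counts as rolling (accumulation requires the
   range to stay strictly below the limit), while the flat rule below uses
   a non-strict bound — the two rules are stated with those inequalities.
2. **Local-high exclusion.** A focal point strictly shallower than the
   shallowest point on *each* side of the window is a local topographic
   high: no rubble. Profile end points, having an empty side, are never
   highs.
3. **Accumulation.** Rubble accumulates if either
   - *depression rule*: the shallowest point on each side is at least
     `rubble_height_m` (base 0.5 m) shallower than the focal point, i.e. a
     problematic rubble layer fits below both flanks; an empty side can
     never satisfy this; or
   - *flat rule*: `range <= flat_depth_change_m` (base 0.5 m).

The four parameters have physical readings: the window is the spatial scale
over which slope matters for rolling; the rubble height is the minimum
layer thickness that impedes coral recovery (also the depth a depression
must offer); the roll range is the relief (about 5 m) beyond which field
observations show rubble rolling off structures; the flat change is the
largest depth variation still read as "flat" given that satellite-derived
bathymetry cannot resolve changes much below 0.5 m.

Points are classed shallow (`< 10` m) or deep, and a transect's *potential
rubble cover* is the percentage of its points flagged, overall and per
section. Flagged points are also "filled" (depth reduced by one rubble
height) to give the post-accumulation profile.

Some branch details are genuinely open choices; the package fixes them as
follows and tests them as stated:

- the depth range is max minus min over the **whole window**, not per side
  and not consecutive differences;
- the depression rule examines the **whole window side**, not only the
  immediate neighbours;
- a point may satisfy the depression rule when the window relief exceeds
  the flat limit but stays below the roll limit — the depression and flat
  rules are an OR;
- windows truncate at profile ends; a missing side fails the depression
  rule but leaves the flat rule available;
- non-multiples of the 10-m lattice (e.g. a 60-m window from a +20%
  scenario) round to the nearest whole sample per side.

## Transect sampling

Profiles are either supplied as tables or extracted from a gridded
bathymetry (10-m cells, the resolution of the satellite-derived source the
design targets): depths are sampled by bilinear interpolation at 10-m steps
along each 500-m transect, both ends are truncated where depth is at or
above the 2-m limit (reef crest and flat; interior shallow points are
kept — only the ends are truncated), and each transect is assigned to the
nearest reef polygon within a 1000-m search radius (distance to the
boundary, zero inside). Transect generation itself is reduced to normals
placed every 500 m along a supplied axis polyline; deriving centrelines
from geomorphic zonation polygons is proprietary-GIS territory and is not
re-implemented.

Aspect — the compass direction a slope faces — is computed per cell with
Horn's 3x3 finite-difference gradient on elevation (the estimator behind
the standard GIS Aspect tool), and a transect's mean aspect is the
*circular* mean of the cells within 10 m of its line:
`[360 + atan2(s, c) * 180/pi] mod 360` with `s`, `c` the mean sine and
cosine. Classes are the 45°-centred quadrants N = [315°,360°) ∪ [0°,45°),
E = [45°,135°), S = [135°,225°), W = [225°,315°), half-open at every
boundary. The class boundaries are a package choice — the quadrants are
centred on the cardinal directions, which is the natural reading but not a
published convention.

## Reef and region metrics

Reef susceptibility at threshold *t* is the percentage of the reef's
transects whose cover is **strictly greater** than *t* ("higher than" is
read as strict; a transect exactly at the threshold does not count).
Thresholds run 10-90% by 10, with 30/40/50% treated as the critical values
for ranking. The *linear distance* converts exceeding-transect counts to
kilometres of slope (count x 500-m spacing; 10 transects = 5 km). The
region summary counts reefs containing at least one problematic transect
per threshold (summing linear distance over **all** reefs), and separately
the reefs with zero rubble potential anywhere. The most susceptible
`ceiling(0.1 n)` reefs are ranked in descending susceptibility with ties
broken by reef id; without a deterministic tie-break the
ranking-sensitivity numbers below would not be reproducible.

## Sensitivity analysis

The one-at-a-time design perturbs each parameter by ±20% (others at base)
and reruns everything. *Count sensitivity* is the mean absolute percentage
change in the reef count relative to base, over both directions and all
thresholds; thresholds whose base count is zero have an undefined relative
change and are excluded by default (`zero_base = "include"` instead counts
them as 0% when the scenario count is also zero — both readings of a
zero-base threshold are defensible, so both are provided). *Ranking
sensitivity* follows each base-case top-decile reef into the scenario's
top-decile list (rank `k + 1` if it dropped out) and averages the absolute
rank changes per threshold, with a standard error across the reef-level
changes. Parameters are ranked by count sensitivity, ties broken by
ranking sensitivity and then name. Percentage changes are reported as
magnitudes; signed changes remain available in the detail table.

## The beta-mixture regression

Depth/aspect effects on cover are modelled on one observation per transect
x depth-section with defined cover. Covers in [0,1] are first compressed
with `(y (n-1) + 0.5) / n` so a beta likelihood applies. Because the
cover distribution is strongly bimodal (many near-zero transects, a
rubble-prone tail), a single beta regression misfits; the package fits a
two-component mixture

```
f(y) = pi * Beta(y; mu_1, phi_1) + (1 - pi) * Beta(y; mu_2, phi_2),
logit(mu_k) = x' beta_k
```

with dummy-coded depth (reference shallow) and aspect (reference N) and a
covariate-free precision per component. Estimation is EM: E-step posterior
responsibilities, M-step weighted beta-regression updates (BFGS with
analytic gradients) and the mixing weight; the observed-data log-likelihood
is checked to be non-decreasing at every iteration. Initialisation is
k-means on the logit responses plus seeded random restarts (10 by default);
short runs are triaged by likelihood and the best is iterated to a relative
tolerance of 1e-8 (at most 1000 iterations). Components are reported
sorted by intercept so labels are identifiable. Standard errors come from
the observed information — a numerical Hessian of the full mixture
likelihood over all 13 parameters — giving Wald z and two-sided p per
coefficient. Observations are hard-assigned by maximum posterior (ties to
component 1), and the depth x aspect interaction is tested per assigned
group by a 3-df likelihood-ratio comparison of beta regressions with and
without the interaction terms, the full model warm-started from the
reduced one so the nested likelihood ordering holds numerically.

## The synthetic generators

All tests and the analysis scripts run on data from three generators, each
a pure function of its specification including the seed:

- `make_profile()` lays terrain segments (flat, ramp, depression, drop-off,
  topographic high) on the 10-m lattice; every segment realises its
  declared relief *exactly* before noise, so decision-tree tests have exact
  geometry to reason about. Noise is additive Gaussian, truncated to keep
  depths below the surface, and off by default in algorithm tests.
- `make_reef_grid()` builds an annular platform (crest ring, interior
  lagoon, monotone outer slope) or a ribbon reef (north-south crest,
  west-facing slope) on 10-m cells, for sampling and aspect tests with
  known geometry.
- `simulate_mixture()` draws proportion data from the two-component
  beta-regression mixture with chosen coefficients, precisions and mixing
  weight, recording the true component of every observation.

These emulate the *features* the algorithm keys on, not real reef
bathymetry: noise is white rather than spatially structured, segments are
piecewise linear, and grids are idealised single reefs. Passing tests
therefore demonstrate that the algorithm and its aggregation arithmetic are
implemented as specified and behave correctly on controlled terrain — not
that the base-case parameters are well calibrated for any particular reef
province, which only field validation can show.

## Problem sizes and numerical choices

The bundled analyses use 40 reefs x 10 transects (about 15,000 depth
samples) for the regional metrics and sensitivity analysis, a 100 x 60-cell
ribbon grid with 10 transects for the sampling stage, and n = 5000
observations for the mixture recovery — sizes at which every property of
interest is already exercised and a full run stays comfortably
interactive. Brute-force equivalence of the vectorised classifier against
a naive per-point reference is checked on 1000 random profiles, and
monotonicity of cover in each tolerance parameter on 200.

Other numerical details: beta means are clamped to [1e-10, 1 - 1e-10]
inside likelihoods; simulated proportions are clamped away from exact 0/1;
the circular mean returns NA when the resultant vector is shorter than
1e-9 (e.g. two opposite aspects); flat cells (zero Horn gradient) have
undefined aspect and are dropped from buffer means; and profiles whose
truncation leaves fewer than two points are discarded.

## Limitations

Beyond the scope limits already stated (no hydrodynamics, no rubble
transport or stabilisation, no volume estimates), the model inherits the
resolution floor of 10-m satellite bathymetry: spur-and-groove systems,
which trap rubble in reality, are invisible at this scale, so
susceptibility is likely underestimated on wave-exposed slopes. The
critical cover thresholds (30/40/50%) are field-motivated but not
experimentally established. The regression reports logit-scale
coefficients with model-based means; marginal back-transformed summaries
depend on reporting conventions that are not standardised, so none are
baked in.
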