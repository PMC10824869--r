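# reefrubble

Transect-based screening of coral reefs for susceptibility to rubble
accumulation.

## The problem

After cyclones and mass bleaching, dead coral erodes into loose rubble.
Mobile rubble abrades and smothers coral recruits, so reefs whose slopes
*retain* rubble can stall in a degraded state for decades. Where rubble can
collect is largely a question of slope morphology: it settles in
depressions and on flat sections of the fore-reef slope, rolls off steep
structure, and cannot rest on local topographic highs. `reefrubble` turns
that observation into a reproducible pipeline for reef managers and
spatial ecologists working with gridded bathymetry: it samples depth
profiles down reef slopes, flags rubble-prone points, and aggregates the
flags into reef- and region-scale susceptibility metrics with a full
parameter sensitivity analysis and a depth-by-aspect regression.

## The model

Depth profiles are sampled every 10 m along 500-m transects (bilinear
interpolation from a 10-m bathymetry grid, both ends truncated at the 2-m
depth limit). Each point `i` is assessed inside a moving window `W_i`
extending 50 m to each side. With `range(W_i) = max depth − min depth`
over the window, point `i` accumulates rubble iff

1. `range(W_i) < d_roll` (else rubble rolls off steep structure), and
2. `i` is not strictly shallower than everything on both sides
   (a local topographic high), and
3. either the shallowest point on *each* side of `i` is at least `h`
   shallower than `i` (a depression deep enough to trap a rubble layer of
   height `h`), or `range(W_i) ≤ d_flat` (a flat section).

Base case: window 50 m, rubble height `h` = 0.5 m, roll range
`d_roll` = 5 m, flat change `d_flat` = 0.5 m. A transect's *potential
rubble cover* is the percentage of its points flagged; a reef's
susceptibility at threshold `t` is the percentage of its transects with
cover strictly above `t`; counts of exceeding transects convert to linear
kilometres of susceptible slope via the 500-m transect spacing. The four
parameters are perturbed ±20% one at a time for sensitivity, and cover is
modelled against depth class and slope aspect with a two-component
beta-regression mixture fitted by EM (see the vignette in
`vignettes/rubble-susceptibility.Rmd` for the full account).

Everything runs on synthetic data from the package's own generators —
terrain profiles with exact segment relief, idealised reef grids, and
beta-mixture proportion data — so no external rasters are required.

## Worked example

```r
library(reefrubble)

# a profile with a rubble-trapping depression, a steep drop-off, and flats
spec <- terrain_spec(list(
  segment("flat", 120),
  segment("depression", 40, 1.2),
  segment("flat", 80),
  segment("dropoff", 60, 6),
  segment("flat", 150)
), base_depth_m = 8)
depths <- make_profile(spec)
evaluate_transect(depths, rubble_params())
#> Transect: 46 points, 22 flagged (47.8% cover; shallow 42.3%, deep 55.0%)
```

The flats and the depression floor are flagged; the drop-off and its
surroundings are not (the 6-m relief exceeds the 5-m roll limit within the
window), and the shallow (< 10 m) and deep sections are scored separately.
Aggregating per-transect covers to a reef:

```r
summ <- data.frame(transect_id = paste0("t", 1:4), reef_id = "Briggs",
                   cover_pct_total = c(0, 35, 52, 61))
reef_susceptibility(summ, thresholds = c(30, 40, 50))
#>   reef_id n_transects threshold n_exceeding pct_exceeding linear_km
#> 1  Briggs           4        30           3            75       1.5
#> 2  Briggs           4        40           2            50       1.0
#> 3  Briggs           4        50           2            50       1.0
```

Three of four transects exceed 30% cover (75%, i.e. 1.5 km of susceptible
slope at 500-m spacing); exceedance is strict, so the 35%-cover transect
does not count at the 40% threshold.

## The analysis workflow

The `analysis/` directory holds the numbered pipeline, each stage a thin
driver over package functions writing its tables under `results/`:

| stage | what it does |
|---|---|
| `01_simulate.R`  | synthetic inputs: ribbon-reef grid (ESRI ASCII), transect lines and reef polygon (GeoJSON), 40-reef profile table (CSV) |
| `02_extract_profiles.R` | bilinear profile sampling, 2-m truncation, reef assignment, circular-mean aspect |
| `03_rubble.R`    | the moving-window classifier at base parameters |
| `04_reef_metrics.R` | reef susceptibility, region summary, top-decile rankings |
| `05_sensitivity.R`  | ±20% one-at-a-time analysis and parameter ranking |
| `06_mixture.R`   | two-component beta-mixture regression with parameter recovery and interaction test |

Run them in order from the repository root, e.g.
`for f in analysis/0*.R; do Rscript $f; done`. The `run_pipeline()`
function performs stages 3-6 in one call with a `pipeline_config()` and
writes a JSON manifest.

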