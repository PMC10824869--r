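#!/usr/bin/env Rscript
# Stage 1: build the synthetic study inputs.
#
# Two kinds of input are produced. First, a small ribbon-reef bathymetry
# grid (10-m cells, west-facing slope) with its transect lines and reef
# polygon, exercising the raster/vector I/O path. Second, a region-scale
# profile table: 40 reefs x 10 transects of mixed terrain (flats, ramps,
# depressions, drop-offs, topographic highs) with mild depth noise,
# standing in for the thousands of slope profiles a full-region run would
# sample.

library(reefrubble)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

## ribbon reef: 100 x 60 cells = 1000 x 600 m
grid <- make_reef_grid(reef_grid_spec(
  c(100, 60), "ribbon", crest_depth_m = 1.5, slope_base_depth_m = 25,
  slope_width_m = 300, noise_sd_m = 0.15, seed = seed))
write_bathymetry_asc(grid, file.path(out, "ribbon_synthetic.asc"))

## transects as normals to a north-south axis over the slope
axis <- cbind(c(430, 430), c(50, 950))
lines <- make_transects(axis, spacing_m = 100, length_m = 500)
features <- lapply(lines, function(l) {
  list(type = "Feature", properties = list(id = l$id),
       geometry = list(type = "LineString",
                       coordinates = list(as.numeric(l$start),
                                          as.numeric(l$end))))
})
jsonlite::write_json(list(type = "FeatureCollection", features = features),
                     file.path(out, "transects_synthetic.geojson"),
                     auto_unbox = TRUE, digits = NA)

## one reef polygon enclosing the ribbon slope
ring <- list(list(150, 0), list(600, 0), list(600, 1000), list(150, 1000),
             list(150, 0))
jsonlite::write_json(list(type = "FeatureCollection", features = list(
  list(type = "Feature", properties = list(reef_id = "RIBBON01"),
       geometry = list(type = "Polygon", coordinates = list(ring))))),
  file.path(out, "reefs_synthetic.geojson"), auto_unbox = TRUE, digits = NA)

## region-scale profile table: 40 reefs x 10 transects
random_terrain <- function(s) {
  set.seed(s)
  n_seg <- sample(3:7, 1)
  segs <- lapply(seq_len(n_seg), function(i) {
    kind <- sample(c("flat", "ramp", "depression", "dropoff", "high"), 1,
                   prob = c(0.35, 0.2, 0.2, 0.15, 0.1))
    len <- 10 * sample(3:12, 1)
    relief <- switch(kind, flat = 0, ramp = runif(1, 0.2, 3),
                     depression = runif(1, 0.3, 2.5),
                     dropoff = runif(1, 4, 8), high = runif(1, 0.3, 2))
    segment(kind, len, relief)
  })
  terrain_spec(segs, base_depth_m = runif(1, 6, 18), noise_sd_m = 0.3,
               seed = s)
}
rows <- list(); k <- 0
for (r in 1:40) {
  for (t in 1:10) {
    k <- k + 1
    d <- make_profile(random_terrain(seed * 1000 + k))
    rows[[k]] <- data.frame(transect_id = sprintf("R%02d_T%02d", r, t),
                            reef_id = sprintf("R%02d", r),
                            distance_m = (seq_along(d) - 1) * 10,
                            depth_m = as.numeric(d))
  }
}
profiles <- do.call(rbind, rows)
write_profiles(profiles, file.path(out, "region_profiles.csv"))

cat("Synthetic inputs written to", out, "\n")
cat(sprintf("  ribbon grid: %d x %d cells, depths %.1f-%.1f m\n",
            nrow(grid$depth), ncol(grid$depth),
            min(grid$depth), max(grid$depth)))
cat(sprintf("  %d transect lines, 1 reef polygon\n", length(lines)))
cat(sprintf("  region table: %d profiles, %d depth samples\n",
            length(unique(profiles$transect_id)), nrow(profiles)))
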