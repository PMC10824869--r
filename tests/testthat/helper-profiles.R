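# Random terrain specifications for property-style tests: a handful of
# segments mixing flats, ramps, depressions, drop-offs and highs, with mild
# depth noise to roughen the lattice.
random_terrain_spec <- function(seed, noise_sd_m = 0.3) {
  set.seed(seed)
  n_seg <- sample(3:7, 1)
  segs <- lapply(seq_len(n_seg), function(i) {
    kind <- sample(c("flat", "ramp", "depression", "dropoff", "high"), 1,
                   prob = c(0.35, 0.2, 0.2, 0.15, 0.1))
    len <- 10 * sample(3:12, 1)
    relief <- switch(kind,
                     flat = 0,
                     ramp = runif(1, 0.2, 3),
                     depression = runif(1, 0.3, 2.5),
                     dropoff = runif(1, 4, 8),
                     high = runif(1, 0.3, 2))
    segment(kind, len, relief)
  })
  terrain_spec(segs, base_depth_m = runif(1, 6, 18),
               noise_sd_m = noise_sd_m, seed = seed)
}

random_profile <- function(seed, noise_sd_m = 0.3) {
  make_profile(random_terrain_spec(seed, noise_sd_m))
}

# A small synthetic reef system: `n_reefs` reefs, each a handful of
# transect profiles with heterogeneous terrain, as a long profile table.
synthetic_reef_profiles <- function(n_reefs = 12, transects_per_reef = 8,
                                    seed = 1) {
  rows <- list()
  k <- 0
  for (r in seq_len(n_reefs)) {
    for (t in seq_len(transects_per_reef)) {
      k <- k + 1
      d <- random_profile(seed * 10000 + k)
      rows[[k]] <- data.frame(
        transect_id = sprintf("R%02d_T%02d", r, t),
        reef_id = sprintf("R%02d", r),
        distance_m = (seq_along(d) - 1) * 10,
        depth_m = as.numeric(d)
      )
    }
  }
  do.call(rbind, rows)
}
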