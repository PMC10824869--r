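# Independent brute-force reference for the rubble decision tree: a direct
# per-point transcription of the rules, deliberately written with plain
# loops and any()/all() so it shares no code with the package's vectorised
# implementation.
oracle_flag <- function(depths, i, params) {
  n <- length(depths)
  h <- round(params$moving_window_m / 10)
  idx <- max(1, i - h):min(n, i + h)
  win <- depths[idx]
  if ((max(win) - min(win)) >= params$roll_depth_range_m) return(FALSE)
  focal <- depths[i]
  left <- depths[idx[idx < i]]
  right <- depths[idx[idx > i]]
  if (length(left) > 0 && length(right) > 0 &&
      all(focal < left) && all(focal < right)) {
    return(FALSE)  # local topographic high
  }
  depression <- length(left) > 0 && length(right) > 0 &&
    any(focal - left >= params$rubble_height_m) &&
    any(focal - right >= params$rubble_height_m)
  flat <- (max(win) - min(win)) <= params$flat_depth_change_m
  depression || flat
}

oracle_transect <- function(depths, params) {
  vapply(seq_along(depths), function(i) oracle_flag(depths, i, params),
         logical(1))
}

# Horn gradient for a single interior cell, hand-spelled for cross-checking
# cell_aspect. z is elevation (negated depth); rows north to south.
oracle_horn_aspect <- function(z, r, c, cell = 10) {
  a <- z[r - 1, c - 1]; b <- z[r - 1, c]; cc <- z[r - 1, c + 1]
  d <- z[r, c - 1];                        f <- z[r, c + 1]
  g <- z[r + 1, c - 1]; h <- z[r + 1, c]; i <- z[r + 1, c + 1]
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cell)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cell)
  if (abs(dzdx) < 1e-12 && abs(dzdy) < 1e-12) return(NA_real_)
  (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
}
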