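#' Indices covered by the moving window around a focal point
#'
#' The window extends `moving_window_m` to both sides of the focal point
#' along-track (5 samples each side at the 50-m base case) and truncates at
#' the profile ends.
#'
#' @param profile_length Number of points in the profile.
#' @param focal_index 1-based index of the focal point.
#' @param moving_window_m Window half-width in metres.
#' @param spacing_m Sample spacing (default 10 m).
#' @return Integer vector of indices, including the focal point.
#' @export
window_indices <- function(profile_length, focal_index, moving_window_m,
                           spacing_m = 10) {
  if (focal_index < 1 || focal_index > profile_length) {
    stop("focal_index out of range", call. = FALSE)
  }
  h <- window_half_width(moving_window_m, spacing_m)
  seq.int(max(1L, focal_index - h), min(profile_length, focal_index + h))
}

#' Does rubble accumulate at one focal point?
#'
#' Applies the moving-window decision tree at a single profile point.
#' Within the window (focal point included) the point accumulates rubble
#' iff:
#' \enumerate{
#'   \item the depth range (max - min) is below the roll limit — otherwise
#'     the point is on or near a steep slope and rubble rolls away;
#'   \item the focal point is not a local topographic high, i.e. not
#'     strictly shallower than the shallowest point on each side;
#'   \item it sits in a depression — the shallowest point on each side is
#'     at least one rubble height shallower than the focal point, so a
#'     problematic rubble layer fits below the flanks — or on a flat,
#'     where the window's depth range does not exceed the flat limit.
#' }
#' A profile end has one empty side: an empty side can never satisfy the
#' depression condition (and an end point is never a local high), but the
#' flat condition still applies.
#'
#' @param depths Numeric profile depths (positive-down m, 10-m spacing).
#' @param focal_index 1-based focal point index.
#' @param params A [rubble_params()].
#' @return `TRUE` (accumulates) or `FALSE` (no rubble).
#' @export
evaluate_focal_point <- function(depths, focal_index, params) {
  stopifnot(inherits(params, "rubble_params"))
  n <- length(depths)
  if (n < 2) stop("profile needs at least 2 points", call. = FALSE)
  idx <- window_indices(n, focal_index, params$moving_window_m)
  win <- depths[idx]
  if (max(win) - min(win) >= params$roll_depth_range_m) return(FALSE)
  focal <- depths[focal_index]
  left <- win[idx < focal_index]
  right <- win[idx > focal_index]
  min_l <- if (length(left)) min(left) else Inf
  min_r <- if (length(right)) min(right) else Inf
  is_high <- length(left) > 0 && length(right) > 0 &&
    focal < min_l && focal < min_r
  if (is_high) return(FALSE)
  depression <- min_l <= focal - params$rubble_height_m &&
    min_r <= focal - params$rubble_height_m
  flat <- max(win) - min(win) <= params$flat_depth_change_m
  depression || flat
}

# Vectorised per-point evaluation of one profile: same decision tree as
# evaluate_focal_point, computed for every point at once with shifted
# copies of the depth vector (O(n * window) with no per-point loop).
.evaluate_points <- function(depths, params) {
  n <- length(depths)
  if (n < 2) stop("profile needs at least 2 points", call. = FALSE)
  if (anyNA(depths)) stop("profile contains missing depths", call. = FALSE)
  h <- window_half_width(params$moving_window_m)
  left_min <- rep(Inf, n); right_min <- rep(Inf, n)
  win_min <- depths; win_max <- depths
  for (k in seq_len(min(h, n - 1L))) {
    lag_k <- c(rep(NA_real_, k), depths[seq_len(n - k)])    # point k to the left
    lead_k <- c(depths[seq.int(k + 1, length.out = n - k)], rep(NA_real_, k))
    left_min <- pmin(left_min, lag_k, na.rm = TRUE)
    right_min <- pmin(right_min, lead_k, na.rm = TRUE)
    win_min <- pmin(win_min, lag_k, lead_k, na.rm = TRUE)
    win_max <- pmax(win_max, lag_k, lead_k, na.rm = TRUE)
  }
  rng <- win_max - win_min
  has_left <- seq_len(n) > 1
  has_right <- seq_len(n) < n
  roll <- rng >= params$roll_depth_range_m
  high <- has_left & has_right & depths < left_min & depths < right_min
  depression <- left_min <= depths - params$rubble_height_m &
    right_min <= depths - params$rubble_height_m
  flat <- rng <= params$flat_depth_change_m
  !roll & !high & (depression | flat)
}

#' Evaluate rubble accumulation along one transect
#'
#' Scans every 10-m point of a profile with the moving-window decision tree,
#' splits points into shallow (< 10 m) and deep sections, computes percent
#' potential rubble cover overall and per section, and fills flagged points
#' with one rubble height (depth decreases by `rubble_height_m` where rubble
#' accumulates).
#'
#' @param depths Numeric profile depths (positive-down m at 10-m spacing).
#' @param params A [rubble_params()].
#' @param shallow_limit_m Depth splitting shallow from deep sections
#'   (default 10 m; shallow is strictly less).
#' @return A list of class `transect_result` with elements `flag` (logical
#'   per point), `section` (`"shallow"`/`"deep"`), `filled` (filled profile),
#'   `n_points`, `n_flagged`, `cover_pct_total`, `cover_pct_shallow`,
#'   `cover_pct_deep` (NA when a section has no points).
#' @export
evaluate_transect <- function(depths, params = rubble_params(),
                              shallow_limit_m = 10) {
  depths <- as.numeric(depths)
  flag <- .evaluate_points(depths, params)
  section <- ifelse(depths < shallow_limit_m, "shallow", "deep")
  filled <- ifelse(flag, depths - params$rubble_height_m, depths)
  pct <- function(sel) {
    if (!any(sel)) return(NA_real_)
    100 * sum(flag[sel]) / sum(sel)
  }
  structure(
    list(flag = flag, section = section, filled = filled,
         n_points = length(depths), n_flagged = sum(flag),
         cover_pct_total = 100 * sum(flag) / length(depths),
         cover_pct_shallow = pct(section == "shallow"),
         cover_pct_deep = pct(section == "deep")),
    class = "transect_result"
  )
}

#' @export
print.transect_result <- function(x, ...) {
  cat(sprintf(
    "Transect: %d points, %d flagged (%.1f%% cover; shallow %s, deep %s)\n",
    x$n_points, x$n_flagged, x$cover_pct_total,
    ifelse(is.na(x$cover_pct_shallow), "-",
           sprintf("%.1f%%", x$cover_pct_shallow)),
    ifelse(is.na(x$cover_pct_deep), "-", sprintf("%.1f%%", x$cover_pct_deep))
  ))
  invisible(x)
}

#' Evaluate rubble accumulation for a table of profiles
#'
#' Applies [evaluate_transect()] to every transect in a long profile table.
#'
#' @param profiles data.frame with columns `transect_id`, `reef_id`,
#'   `distance_m`, `depth_m`.
#' @param params A [rubble_params()].
#' @param shallow_limit_m Shallow/deep split depth.
#' @return List with `points` (per-point data.frame adding `flag`, `section`,
#'   `filled_depth_m`) and `summary` (one row per transect: `transect_id`,
#'   `reef_id`, `n_points`, `n_flagged`, `cover_pct_total`,
#'   `cover_pct_shallow`, `cover_pct_deep`).
#' @export
evaluate_profiles <- function(profiles, params = rubble_params(),
                              shallow_limit_m = 10) {
  req <- c("transect_id", "reef_id", "distance_m", "depth_m")
  if (!all(req %in% names(profiles))) {
    stop("profiles must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(profiles$transect_id)
  pts <- vector("list", length(ids))
  summ <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    sub <- profiles[profiles$transect_id == ids[k], , drop = FALSE]
    sub <- sub[order(sub$distance_m), , drop = FALSE]
    res <- evaluate_transect(sub$depth_m, params, shallow_limit_m)
    pts[[k]] <- cbind(sub, flag = res$flag, section = res$section,
                      filled_depth_m = res$filled)
    summ[[k]] <- data.frame(
      transect_id = ids[k], reef_id = sub$reef_id[1],
      n_points = res$n_points, n_flagged = res$n_flagged,
      cover_pct_total = res$cover_pct_total,
      cover_pct_shallow = res$cover_pct_shallow,
      cover_pct_deep = res$cover_pct_deep
    )
  }
  list(points = do.call(rbind, pts), summary = do.call(rbind, summ))
}
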