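#' Linear distance of susceptible reef slope
#'
#' The count of transects exceeding a cover threshold multiplied by the
#' spacing between transects, reported in kilometres: ten susceptible
#' transects 500 m apart span 5 km of reef slope.
#'
#' @param count_exceeding Number of transects exceeding the threshold.
#' @param spacing_m Transect spacing in metres (default 500).
#' @return Linear distance in km.
#' @examples
#' linear_distance(10)  # 5
#' @export
linear_distance <- function(count_exceeding, spacing_m = 500) {
  if (any(count_exceeding < 0)) stop("count must be >= 0", call. = FALSE)
  count_exceeding * spacing_m / 1000
}

#' Reef-level susceptibility to rubble accumulation
#'
#' For every reef and every cover threshold, the percentage of the reef's
#' transects whose potential rubble cover is strictly higher than the
#' threshold, together with the corresponding linear distance.
#'
#' @param summary Per-transect summary (from [evaluate_profiles()]`$summary`)
#'   with columns `reef_id` and `cover_pct_total`; unassigned transects
#'   (NA reef) are dropped.
#' @param thresholds Cover thresholds in percent (default 10-90 by 10).
#' @param spacing_m Transect spacing for the linear-distance metric.
#' @return data.frame with one row per reef x threshold: `reef_id`,
#'   `n_transects`, `threshold`, `n_exceeding`, `pct_exceeding`, `linear_km`.
#' @export
reef_susceptibility <- function(summary, thresholds = seq(10, 90, by = 10),
                                spacing_m = 500) {
  if (!all(c("reef_id", "cover_pct_total") %in% names(summary))) {
    stop("summary needs columns reef_id and cover_pct_total", call. = FALSE)
  }
  keep <- !is.na(summary$reef_id)
  if (!all(keep)) {
    warning(sum(!keep), " transects without a reef assignment dropped")
    summary <- summary[keep, , drop = FALSE]
  }
  if (nrow(summary) == 0) {
    warning("no assigned transects; empty susceptibility table")
    return(data.frame(reef_id = character(0), n_transects = integer(0),
                      threshold = numeric(0), n_exceeding = integer(0),
                      pct_exceeding = numeric(0), linear_km = numeric(0)))
  }
  reefs <- sort(unique(summary$reef_id))
  out <- expand.grid(reef_id = reefs, threshold = thresholds,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$reef_id, out$threshold), ]
  covers <- split(summary$cover_pct_total, summary$reef_id)
  n_tr <- vapply(covers, length, integer(1))
  out$n_transects <- n_tr[out$reef_id]
  out$n_exceeding <- mapply(function(r, t) sum(covers[[r]] > t),
                            out$reef_id, out$threshold)
  out$pct_exceeding <- 100 * out$n_exceeding / out$n_transects
  out$linear_km <- linear_distance(out$n_exceeding, spacing_m)
  rownames(out) <- NULL
  out[, c("reef_id", "n_transects", "threshold", "n_exceeding",
          "pct_exceeding", "linear_km")]
}

#' Region-wide susceptibility summary
#'
#' Aggregates reef susceptibility across the whole region: per threshold,
#' the number and percentage of reefs containing at least one problematic
#' transect (cover strictly above the threshold) and the total linear
#' distance of susceptible slope. Also reports the reefs with zero
#' potential rubble cover anywhere — those excluded from susceptibility
#' mapping altogether.
#'
#' @param susceptibility Output of [reef_susceptibility()].
#' @param summary Per-transect summary (to identify zero-rubble reefs).
#' @return List with `by_threshold` (data.frame: `threshold`, `n_reefs`,
#'   `pct_reefs`, `total_linear_km`) and `excluded` (list: `n_reefs_total`,
#'   `n_zero_rubble`, `pct_zero_rubble`).
#' @export
gbr_summary <- function(susceptibility, summary) {
  thresholds <- sort(unique(susceptibility$threshold))
  by_thr <- do.call(rbind, lapply(thresholds, function(t) {
    sub <- susceptibility[susceptibility$threshold == t, ]
    n_reefs_total <- length(unique(sub$reef_id))
    data.frame(
      threshold = t,
      n_reefs = sum(sub$n_exceeding >= 1),
      pct_reefs = 100 * sum(sub$n_exceeding >= 1) / n_reefs_total,
      total_linear_km = sum(sub$linear_km)
    )
  }))
  summary <- summary[!is.na(summary$reef_id), , drop = FALSE]
  max_cover <- tapply(summary$cover_pct_total, summary$reef_id, max)
  n_total <- length(max_cover)
  n_zero <- sum(max_cover == 0)
  list(
    by_threshold = by_thr,
    excluded = list(
      n_reefs_total = n_total,
      n_zero_rubble = n_zero,
      pct_zero_rubble = round(100 * n_zero / n_total, 1)
    )
  )
}

#' Rank the most susceptible reefs (top decile)
#'
#' Orders reefs by decreasing percentage of transects exceeding the given
#' threshold — the greater the percentage, the higher the ranking — and
#' returns the top 10% (ceiling). Ties are broken by reef id so rankings
#' are reproducible.
#'
#' @param susceptibility Output of [reef_susceptibility()].
#' @param threshold Cover threshold to rank at (must be present).
#' @param top_fraction Fraction of reefs returned (default 0.1).
#' @return data.frame `reef_id`, `pct_exceeding`, `rank` (1 = most
#'   susceptible), restricted to the top decile. With fewer than 10 reefs
#'   the whole ranked list is returned with a warning.
#' @export
rank_top_decile <- function(susceptibility, threshold, top_fraction = 0.1) {
  sub <- susceptibility[susceptibility$threshold == threshold, , drop = FALSE]
  if (nrow(sub) == 0) stop("threshold ", threshold, " not in table",
                           call. = FALSE)
  n <- nrow(sub)
  ord <- order(-sub$pct_exceeding, sub$reef_id)
  ranked <- sub[ord, c("reef_id", "pct_exceeding")]
  ranked$rank <- seq_len(n)
  k <- ceiling(top_fraction * n)
  if (n < 10) {
    warning("fewer than 10 reefs; returning the full ranked list")
    k <- n
  }
  out <- ranked[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
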