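#' One-at-a-time sensitivity analysis of the rubble algorithm
#'
#' Reruns the transect-to-reef pipeline with each of the four algorithm
#' parameters perturbed by +/- `perturbation` (20% by default), the other
#' three held at the base case, and stores the per-reef susceptibility
#' tables of every scenario. Scenarios whose scaled parameter violates the
#' parameter invariants are skipped with a warning.
#'
#' @param profiles Long profile table (`transect_id`, `reef_id`,
#'   `distance_m`, `depth_m`).
#' @param base_params Base-case [rubble_params()].
#' @param thresholds Cover thresholds in percent.
#' @param perturbation Relative perturbation (default 0.2).
#' @param spacing_m Transect spacing for linear distances.
#' @return Object of class `oat_result`: `base` (list with `summary`,
#'   `susceptibility`), `runs` (nested list `runs[[parameter]][[scenario]]`
#'   with scenarios `"-20%"`/`"+20%"`), `thresholds`, `perturbation`.
#' @export
run_oat <- function(profiles, base_params = rubble_params(),
                    thresholds = seq(10, 90, by = 10), perturbation = 0.2,
                    spacing_m = 500) {
  pipeline <- function(params) {
    summ <- evaluate_profiles(profiles, params)$summary
    susc <- reef_susceptibility(summ, thresholds, spacing_m)
    list(summary = summ, susceptibility = susc)
  }
  base <- pipeline(base_params)
  par_names <- names(unclass(base_params))
  scen_labels <- c(sprintf("-%d%%", round(100 * perturbation)),
                   sprintf("+%d%%", round(100 * perturbation)))
  factors <- c(1 - perturbation, 1 + perturbation)
  runs <- list()
  for (p in par_names) {
    runs[[p]] <- list()
    for (j in seq_along(factors)) {
      params_j <- tryCatch(scale_param(base_params, p, factors[j]),
                           error = function(e) NULL)
      if (is.null(params_j)) {
        warning("scenario ", scen_labels[j], " for ", p,
                " violates parameter invariants; skipped")
        next
      }
      runs[[p]][[scen_labels[j]]] <- pipeline(params_j)
    }
  }
  structure(list(base = base, runs = runs, thresholds = thresholds,
                 perturbation = perturbation),
            class = "oat_result")
}

# Reef counts (>= 1 transect exceeding) per threshold from a susceptibility
# table.
.reef_counts <- function(susceptibility, thresholds) {
  vapply(thresholds, function(t) {
    sub <- susceptibility[susceptibility$threshold == t, ]
    sum(sub$n_exceeding >= 1)
  }, numeric(1))
}

#' Sensitivity of the susceptible reef count to one parameter
#'
#' Mean absolute percentage change in the number of reefs containing
#' problematic transects, relative to the base case: per threshold and
#' perturbation direction, `100 * |n_scenario - n_base| / n_base`, averaged
#' over both directions and all thresholds. Thresholds with a base count of
#' zero are excluded by default (their relative change is undefined); with
#' `zero_base = "include"` they contribute a 0% change when the scenario
#' count is also zero.
#'
#' @param oat An [run_oat()] result.
#' @param parameter Parameter name.
#' @param zero_base `"exclude"` or `"include"`.
#' @return List: `mean_pct_change` (scalar, NA if undefined everywhere) and
#'   `detail` (data.frame: scenario, threshold, n_base, n_scenario,
#'   pct_change).
#' @export
count_sensitivity <- function(oat, parameter,
                              zero_base = c("exclude", "include")) {
  zero_base <- match.arg(zero_base)
  stopifnot(inherits(oat, "oat_result"))
  n_base <- .reef_counts(oat$base$susceptibility, oat$thresholds)
  rows <- list()
  for (scen in names(oat$runs[[parameter]])) {
    n_s <- .reef_counts(oat$runs[[parameter]][[scen]]$susceptibility,
                        oat$thresholds)
    pct <- ifelse(n_base > 0, 100 * abs(n_s - n_base) / n_base,
                  ifelse(n_s == 0, 0, NA_real_))
    rows[[scen]] <- data.frame(scenario = scen, threshold = oat$thresholds,
                               n_base = n_base, n_scenario = n_s,
                               pct_change = pct)
  }
  detail <- do.call(rbind, rows)
  rownames(detail) <- NULL
  use <- if (zero_base == "exclude") detail$n_base > 0 else !is.na(detail$pct_change)
  mean_pct <- if (any(use)) mean(detail$pct_change[use]) else NA_real_
  list(mean_pct_change = mean_pct, detail = detail)
}

#' Sensitivity of the top-decile reef ranking to one parameter
#'
#' For every threshold, takes the base-case top 10% of reefs (ranked by
#' percentage of transects exceeding the threshold) and measures how far
#' each moves under a perturbed scenario's re-ranking. A base top-decile
#' reef absent from the scenario's top-decile list is assigned rank
#' `length(list) + 1`. The absolute rank changes are averaged per threshold
#' (with a standard error across the reef-level changes of both
#' perturbation directions) and then across thresholds.
#'
#' @param oat An [run_oat()] result.
#' @param parameter Parameter name.
#' @return List: `mean_abs_rank_change` (scalar) and `by_threshold`
#'   (data.frame: threshold, mean_abs_change, se, n).
#' @export
ranking_sensitivity <- function(oat, parameter) {
  stopifnot(inherits(oat, "oat_result"))
  by_thr <- lapply(oat$thresholds, function(t) {
    base_rank <- suppressWarnings(
      rank_top_decile(oat$base$susceptibility, t))
    changes <- c()
    for (scen in names(oat$runs[[parameter]])) {
      scen_rank <- suppressWarnings(
        rank_top_decile(oat$runs[[parameter]][[scen]]$susceptibility, t))
      pos <- match(base_rank$reef_id, scen_rank$reef_id)
      pos[is.na(pos)] <- nrow(scen_rank) + 1L
      changes <- c(changes, abs(base_rank$rank - pos))
    }
    data.frame(threshold = t, mean_abs_change = mean(changes),
               se = if (length(changes) > 1) {
                 sd(changes) / sqrt(length(changes))
               } else NA_real_,
               n = length(changes))
  })
  by_thr <- do.call(rbind, by_thr)
  list(mean_abs_rank_change = mean(by_thr$mean_abs_change),
       by_threshold = by_thr)
}

#' Rank the algorithm parameters by sensitivity
#'
#' Orders the four parameters by decreasing count sensitivity; ties are
#' broken by ranking sensitivity (larger first) and then alphabetically.
#'
#' @param oat An [run_oat()] result.
#' @param zero_base Passed to [count_sensitivity()].
#' @return data.frame: `parameter`, `count_sensitivity_pct`,
#'   `ranking_sensitivity`, `rank`.
#' @export
rank_parameters <- function(oat, zero_base = c("exclude", "include")) {
  zero_base <- match.arg(zero_base)
  pars <- names(oat$runs)
  cs <- vapply(pars, function(p) {
    count_sensitivity(oat, p, zero_base)$mean_pct_change
  }, numeric(1))
  rs <- vapply(pars, function(p) {
    ranking_sensitivity(oat, p)$mean_abs_rank_change
  }, numeric(1))
  ord <- order(-cs, -rs, pars)
  out <- data.frame(parameter = pars[ord],
                    count_sensitivity_pct = cs[ord],
                    ranking_sensitivity = rs[ord],
                    rank = seq_along(pars))
  rownames(out) <- NULL
  out
}
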