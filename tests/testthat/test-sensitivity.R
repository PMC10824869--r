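# Build a susceptibility table where, at each threshold, the first
# `n_with[t]` reefs have exactly one exceeding transect.
build_susc <- function(n_with, thresholds, n_reefs = 15) {
  do.call(rbind, lapply(seq_along(thresholds), function(j) {
    data.frame(reef_id = sprintf("R%02d", 1:n_reefs), n_transects = 10,
               threshold = thresholds[j],
               n_exceeding = as.integer(seq_len(n_reefs) <= n_with[j]),
               pct_exceeding = 10 * as.integer(seq_len(n_reefs) <= n_with[j]),
               linear_km = 0.5 * as.integer(seq_len(n_reefs) <= n_with[j]))
  }))
}

oat_fixture <- function(base, runs, thresholds) {
  structure(list(base = list(susceptibility = base), runs = runs,
                 thresholds = thresholds, perturbation = 0.2),
            class = "oat_result")
}

test_that("OAT bookkeeping: four parameters, two perturbations each", {
  profiles <- synthetic_reef_profiles(n_reefs = 4, transects_per_reef = 4,
                                      seed = 3)
  oat <- run_oat(profiles, thresholds = c(30, 50))
  expect_named(oat$runs, c("moving_window_m", "rubble_height_m",
                           "roll_depth_range_m", "flat_depth_change_m"))
  n_runs <- sum(vapply(oat$runs, length, integer(1)))
  expect_equal(n_runs, 8)
  expect_true(all(vapply(oat$runs, function(r) {
    identical(names(r), c("-20%", "+20%"))
  }, logical(1))))
})

test_that("a zero-percent perturbation reproduces the base case exactly", {
  profiles <- synthetic_reef_profiles(n_reefs = 5, transects_per_reef = 4,
                                      seed = 8)
  oat <- run_oat(profiles, perturbation = 0)
  for (p in names(oat$runs)) {
    for (scen in names(oat$runs[[p]])) {
      expect_identical(oat$runs[[p]][[scen]]$susceptibility,
                       oat$base$susceptibility)
    }
    expect_equal(count_sensitivity(oat, p)$mean_pct_change, 0)
    expect_equal(ranking_sensitivity(oat, p)$mean_abs_rank_change, 0)
  }
  # scaling a parameter by 1 is the identity on the parameter set
  base <- rubble_params()
  expect_identical(scale_param(base, "moving_window_m", 1), base)
})

test_that("count sensitivity matches hand-computed means", {
  thr <- c(30, 40, 50)
  oat <- oat_fixture(
    build_susc(c(10, 5, 0), thr),
    list(moving_window_m = list(
      "-20%" = list(susceptibility = build_susc(c(12, 4, 0), thr)),
      "+20%" = list(susceptibility = build_susc(c(8, 5, 0), thr))
    )),
    thr
  )
  cs <- count_sensitivity(oat, "moving_window_m")
  # pct changes: 20 and 20 at t=30; 20 and 0 at t=40; t=50 excluded (base 0)
  expect_equal(cs$mean_pct_change, 15)
  expect_equal(cs$detail$pct_change[cs$detail$threshold == 30], c(20, 20))
  # inclusion mode counts the 0-change zero-base threshold
  cs_inc <- count_sensitivity(oat, "moving_window_m", zero_base = "include")
  expect_equal(cs_inc$mean_pct_change, 10)
})

test_that("count sensitivity reproduces the 336-to-235 style arithmetic", {
  thr <- 30
  oat <- oat_fixture(
    build_susc(336, thr, n_reefs = 400),
    list(moving_window_m = list(
      "+20%" = list(susceptibility = build_susc(235, thr, n_reefs = 400))
    )),
    thr
  )
  cs <- count_sensitivity(oat, "moving_window_m")
  expect_equal(cs$mean_pct_change, 100 * (336 - 235) / 336, tolerance = 1e-12)
  expect_equal(round(cs$mean_pct_change, 2), 30.06)
})

test_that("count sensitivity is scale-free in the number of reefs", {
  thr <- c(30, 40)
  oat1 <- oat_fixture(
    build_susc(c(6, 3), thr, n_reefs = 10),
    list(p = list("+20%" = list(susceptibility = build_susc(c(4, 3), thr,
                                                            n_reefs = 10)))),
    thr)
  oat2 <- oat_fixture(
    build_susc(c(12, 6), thr, n_reefs = 20),
    list(p = list("+20%" = list(susceptibility = build_susc(c(8, 6), thr,
                                                            n_reefs = 20)))),
    thr)
  expect_equal(count_sensitivity(oat1, "p")$mean_pct_change,
               count_sensitivity(oat2, "p")$mean_pct_change)
})

test_that("ranking sensitivity averages absolute rank changes", {
  # 100 reefs; base top decile is Q001..Q010 with ranks 1..10
  pcts <- stats::setNames(seq(100, 1), sprintf("Q%03d", 1:100))
  mk <- function(p) {
    data.frame(reef_id = names(p), n_transects = 10, threshold = 40,
               n_exceeding = 1, pct_exceeding = as.numeric(p),
               linear_km = 0.5)
  }
  moved <- pcts; moved["Q001"] <- 95.5   # falls from rank 1 to rank 5
  oat <- oat_fixture(
    mk(pcts),
    list(p = list("-20%" = list(susceptibility = mk(moved)),
                  "+20%" = list(susceptibility = mk(pcts)))),
    40)
  rs <- ranking_sensitivity(oat, "p")
  # moved scenario: |dr| = 4,1,1,1,1,0,...; identical scenario: all 0
  expect_equal(rs$mean_abs_rank_change, 0.4)
  expect_equal(rs$by_threshold$n, 20)

  # a base top-decile reef absent from the scenario list gets rank k + 1
  gone <- pcts; gone["Q001"] <- 0
  oat2 <- oat_fixture(
    mk(pcts),
    list(p = list("+20%" = list(susceptibility = mk(gone)))),
    40)
  rs2 <- ranking_sensitivity(oat2, "p")
  # |dr|: Q001 -> 11 - 1 = 10; Q002..Q010 move up one rank each
  expect_equal(rs2$mean_abs_rank_change, (10 + 9) / 10)
})

test_that("widening the window on drop-off terrain cannot add reefs", {
  segs <- function(shift) list(segment("flat", 150 + shift),
                               segment("dropoff", 40, 6),
                               segment("flat", 150))
  rows <- list()
  for (r in 1:6) {
    d <- make_profile(terrain_spec(segs(10 * r), base_depth_m = 8 + r / 2))
    rows[[r]] <- data.frame(transect_id = sprintf("T%d", r),
                            reef_id = sprintf("R%d", r),
                            distance_m = (seq_along(d) - 1) * 10,
                            depth_m = as.numeric(d))
  }
  profiles <- do.call(rbind, rows)
  thr <- seq(10, 90, by = 10)
  base <- reef_susceptibility(evaluate_profiles(profiles)$summary, thr)
  wide <- reef_susceptibility(
    evaluate_profiles(profiles,
                      scale_param(rubble_params(), "moving_window_m",
                                  1.2))$summary, thr)
  for (t in thr) {
    n_b <- sum(base$n_exceeding[base$threshold == t] >= 1)
    n_w <- sum(wide$n_exceeding[wide$threshold == t] >= 1)
    expect_lte(n_w, n_b)
  }
})

test_that("parameters are ranked by count then ranking sensitivity", {
  thr <- 30
  mk_runs <- function(counts) {
    lapply(counts, function(n) {
      list("+20%" = list(susceptibility = build_susc(n, thr, n_reefs = 20)))
    })
  }
  base <- build_susc(10, thr, n_reefs = 20)
  # designed ordering: window (50% change) > flat (30%) > height (10%) > roll (0%)
  runs <- mk_runs(list(moving_window_m = 5, rubble_height_m = 9,
                       roll_depth_range_m = 10, flat_depth_change_m = 7))
  oat <- oat_fixture(base, runs, thr)
  rk <- rank_parameters(oat)
  expect_equal(rk$parameter,
               c("moving_window_m", "flat_depth_change_m",
                 "rubble_height_m", "roll_depth_range_m"))
  expect_equal(rk$rank, 1:4)

  # all-equal sensitivities: alphabetical tie-break
  runs_eq <- mk_runs(list(moving_window_m = 10, rubble_height_m = 10,
                          roll_depth_range_m = 10, flat_depth_change_m = 10))
  rk_eq <- rank_parameters(oat_fixture(base, runs_eq, thr))
  expect_equal(rk_eq$parameter, sort(rk_eq$parameter))
})

test_that("scenarios violating parameter invariants are skipped", {
  profiles <- synthetic_reef_profiles(n_reefs = 3, transects_per_reef = 3,
                                      seed = 2)
  # flat limit close below the roll limit: +20% on flat breaks the invariant
  params <- rubble_params(roll_depth_range_m = 5, flat_depth_change_m = 4.5)
  warns <- capture_warnings(oat <- run_oat(profiles, params, thresholds = 30))
  expect_true(any(grepl("skipped", warns)))
  expect_equal(names(oat$runs$flat_depth_change_m), "-20%")
  # the opposite invariant: -20% on the roll limit dips below the flat limit
  expect_equal(names(oat$runs$roll_depth_range_m), "+20%")
})
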