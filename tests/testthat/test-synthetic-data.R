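test_that("flat terrain yields a constant profile at 10-m spacing", {
  p <- make_profile(terrain_spec(list(segment("flat", 500)), 12))
  expect_length(p, 51)
  expect_true(all(p == 12))
  expect_equal(attr(p, "distance_m"), seq(0, 500, by = 10))
})

test_that("depressions and highs realise their relief exactly before noise", {
  sp <- terrain_spec(list(segment("flat", 100),
                          segment("depression", 30, 1),
                          segment("flat", 100)), base_depth_m = 12)
  p <- make_profile(sp)
  expect_equal(max(p), 13)           # exactly one rubble-trapping metre deeper
  expect_equal(p[1], 12)
  expect_equal(p[length(p)], 12)

  sp_h <- terrain_spec(list(segment("flat", 100),
                            segment("high", 40, 2),
                            segment("flat", 100)), base_depth_m = 12)
  expect_equal(min(make_profile(sp_h)), 10)

  sp_r <- terrain_spec(list(segment("ramp", 50, 3)), base_depth_m = 10)
  p_r <- make_profile(sp_r)
  expect_equal(p_r[length(p_r)], 13)  # ramp ends exactly relief deeper
})

test_that("a drop-off produces >= 5 m relief within a 50-m half-window", {
  sp <- terrain_spec(list(segment("flat", 200), segment("dropoff", 50, 6),
                          segment("flat", 200)), base_depth_m = 10)
  p <- make_profile(sp)
  h <- 5
  reliefs <- vapply(seq_along(p), function(i) {
    w <- p[max(1, i - h):min(length(p), i + h)]
    max(w) - min(w)
  }, numeric(1))
  expect_gte(max(reliefs), 5)
})

test_that("profile generation is deterministic in the spec seed", {
  sp <- terrain_spec(list(segment("flat", 300), segment("dropoff", 60, 6)),
                     base_depth_m = 12, noise_sd_m = 0.5, seed = 99)
  expect_identical(make_profile(sp), make_profile(sp))
  sp2 <- terrain_spec(sp$segments, 12, 0.5, seed = 100)
  expect_false(identical(make_profile(sp), make_profile(sp2)))
})

test_that("invalid terrain specs are rejected", {
  expect_error(terrain_spec(list(), 12), "at least one segment")
  expect_error(segment("flat", 55), "multiple of 10")
  expect_error(segment("depression", 50, 0), "relief_m > 0")
  expect_error(terrain_spec(list(segment("flat", 100)), -3), "positive-down")
  # a high rising above sea level is caught at generation time
  expect_error(
    make_profile(terrain_spec(list(segment("high", 40, 5)), 2)),
    "sea level")
})

test_that("annular platform deepens monotonically outward from the crest", {
  g <- make_reef_grid(reef_grid_spec(c(101, 101), "annular_platform",
                                     crest_depth_m = 1.5,
                                     slope_base_depth_m = 25,
                                     slope_width_m = 200))
  m <- g$depth
  centre <- 51
  # sample the eastward radial from the crest ring outwards
  r_idx <- which.min(m[centre, centre:101]) + centre - 1
  radial <- m[centre, r_idx:101]
  expect_true(all(diff(radial) >= -1e-9))
  # crest depth attained up to cell discretisation of the ring radius
  expect_equal(min(m), 1.5, tolerance = 0.05)
  expect_equal(max(m), 25, tolerance = 1e-6)
})

test_that("ribbon slope cells face west", {
  g <- make_reef_grid(reef_grid_spec(c(60, 60), "ribbon",
                                     crest_depth_m = 1.5,
                                     slope_base_depth_m = 25,
                                     slope_width_m = 300))
  a <- cell_aspect(g)
  slope <- a[10:50, 20:40]
  slope <- slope[!is.na(slope)]
  expect_gt(length(slope), 0)
  expect_true(all(slope >= 225 & slope < 315))
})

test_that("reef grids are deterministic under seed and reject tiny shapes", {
  sp <- reef_grid_spec(c(80, 80), "annular_platform", noise_sd_m = 0.2,
                       seed = 5, slope_width_m = 150)
  expect_identical(make_reef_grid(sp)$depth, make_reef_grid(sp)$depth)
  expect_error(reef_grid_spec(c(10, 10), "annular_platform"), "too small")
  expect_error(reef_grid_spec(c(30, 8), "ribbon", slope_width_m = 300),
               "too narrow")
  expect_error(reef_grid_spec(c(50, 50), crest_depth_m = 30,
                              slope_base_depth_m = 25), "shallower")
})

test_that("mixture simulation honours its mixing weight and link", {
  # degenerate single-component case
  d1 <- simulate_mixture(mixture_sim_spec(200, 1, rep(0, 5), rep(1, 5),
                                          c(10, 10), seed = 3))
  expect_true(all(d1$true_component == 1))

  # intercept-only with logit mean 0: sample mean near 0.5
  d2 <- simulate_mixture(mixture_sim_spec(20000, 1, c(0, 0, 0, 0, 0),
                                          rep(0, 5), c(10, 10), seed = 4))
  expect_equal(mean(d2$proportion), 0.5, tolerance = 0.01)
  expect_true(all(d2$proportion > 0 & d2$proportion < 1))

  # component fractions within 2 SE of the mixing weight
  n <- 5000; pi1 <- 0.3
  d3 <- simulate_mixture(mixture_sim_spec(n, pi1, c(-2, 0, 0, 0, 0),
                                          c(1, 0, 0, 0, 0), c(20, 30),
                                          seed = 11))
  se <- sqrt(pi1 * (1 - pi1) / n)
  expect_lt(abs(mean(d3$true_component == 1) - pi1), 2 * se)
})

test_that("mixture marginal mean matches pi * mu1 + (1 - pi) * mu2", {
  b1 <- c(-1.5, 0, 0, 0, 0); b2 <- c(0.8, 0, 0, 0, 0)
  pi1 <- 0.4
  d <- simulate_mixture(mixture_sim_spec(20000, pi1, b1, b2, c(15, 25),
                                         seed = 21))
  expected <- pi1 * plogis(b1[1]) + (1 - pi1) * plogis(b2[1])
  expect_equal(mean(d$proportion), expected, tolerance = 0.01)
})

test_that("invalid mixture specs are rejected", {
  expect_error(mixture_sim_spec(100, 0, rep(0, 5), rep(0, 5), c(1, 1)),
               "pi1")
  expect_error(mixture_sim_spec(100, 0.5, rep(0, 5), rep(0, 5), c(-1, 1)),
               "positive")
  expect_error(mixture_sim_spec(100, 0.5, rep(0, 4), rep(0, 5), c(1, 1)),
               "5 coefficients")
})
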