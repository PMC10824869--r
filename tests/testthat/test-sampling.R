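test_that("bilinear sampling reproduces constants, nodes and midpoints", {
  # constant grid: every sample is the constant
  g <- bathymetry_grid(matrix(12, 20, 20))
  line <- transect_line("t1", c(20, 20), c(170, 170))
  p <- sample_profile(g, line)
  expect_true(all(abs(p - 12) < 1e-12))

  # east-west ramp sampled at a cell centre returns that cell's value
  ramp <- bathymetry_grid(matrix(rep(1:20, times = 20), 20, 20, byrow = TRUE))
  # cell (row 10, col 7) centre is at x = 65, y = (20 - 10 + 0.5) * 10 = 105
  v <- reefrubble:::.interp_bilinear(ramp, 65, 105)
  expect_equal(v, ramp$depth[10, 7])

  # midpoint of four cells valued 10,10,14,14 -> 12 (hand-evaluated)
  quad <- bathymetry_grid(matrix(c(10, 10, 14, 14), 2, 2, byrow = FALSE))
  expect_equal(reefrubble:::.interp_bilinear(quad, 10, 10), 12)
})

test_that("bilinear sampling is exact on a bilinear surface", {
  # depth = a + b x + c y + d x y is reproduced exactly at any sample point
  a <- 5; b <- 0.01; c <- 0.02; d <- 1e-4
  nr <- 25; nc <- 25
  xs <- (seq_len(nc) - 0.5) * 10
  ys <- (nr - seq_len(nr) + 0.5) * 10
  m <- outer(ys, xs, function(y, x) a + b * x + c * y + d * x * y)
  g <- bathymetry_grid(m)
  set.seed(42)
  px <- runif(50, 10, 240); py <- runif(50, 10, 240)
  got <- reefrubble:::.interp_bilinear(g, px, py)
  expect_equal(got, a + b * px + c * py + d * px * py, tolerance = 1e-10)
})

test_that("sampling propagates nodata and rejects lines off the grid", {
  m <- matrix(12, 10, 10)
  m[5, 5] <- NA
  g <- bathymetry_grid(m)
  line <- transect_line("t", c(5, 55), c(95, 55))  # crosses the NA cell
  p <- sample_profile(g, line)
  expect_true(anyNA(p))
  off <- transect_line("t2", c(500, 500), c(600, 600))
  expect_error(sample_profile(g, off), "outside the grid")
})

test_that("truncation strips shallow ends only", {
  expect_equal(as.numeric(truncate_profile(c(1.5, 1.8, 3, 7, 12))),
               c(3, 7, 12))
  expect_equal(as.numeric(truncate_profile(c(3, 7, 12))), c(3, 7, 12))
  # interior shallow point survives: ends-only rule
  expect_equal(as.numeric(truncate_profile(c(1, 5, 1.9, 6, 1))),
               c(5, 1.9, 6))
  full <- truncate_profile(c(0.5, 1, 1.9))
  expect_length(full, 0)
  expect_true(attr(full, "fully_truncated"))
})

test_that("truncation endpoints are below the limit on random profiles", {
  for (s in 1:25) {
    p <- random_profile(s, noise_sd_m = 4)
    kept <- truncate_profile(p)
    if (length(kept) == 0) next
    expect_gt(kept[1], 2)
    expect_gt(kept[length(kept)], 2)
    # interior points untouched: kept is a contiguous slice of the input
    expect_equal(as.numeric(kept), as.numeric(p[attr(kept, "kept")]))
  }
})

test_that("reef assignment picks the nearest polygon within 1000 m", {
  sq <- function(x0, y0, w = 200) {
    cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + w, y0 + w))
  }
  polys <- list(A = sq(0, 0), B = sq(1000, 0))
  inside <- transect_line("in", c(50, 50), c(150, 150))
  expect_equal(assign_reef(inside, polys), "A")
  # 1500 m from the nearest polygon edge: unassigned
  far <- transect_line("far", c(2700, 100), c(3200, 100))
  expect_true(is.na(assign_reef(far, polys)))
  # between two polygons, the nearer one (B at 200 m vs A at 600 m) wins
  near_b <- transect_line("nb", c(800, 100), c(800, 150))
  expect_equal(assign_reef(near_b, polys), "B")
  expect_true(is.na(assign_reef(inside, list())))
})

test_that("aspect of analytic planes matches the cardinal directions", {
  n <- 11
  east <- bathymetry_grid(matrix(rep(1:n, times = n), n, n, byrow = TRUE))
  south <- bathymetry_grid(matrix(rep(1:n, each = n), n, n, byrow = TRUE))
  west <- bathymetry_grid(matrix(rep(n:1, times = n), n, n, byrow = TRUE))
  north <- bathymetry_grid(matrix(rep(n:1, each = n), n, n, byrow = TRUE))
  for (pair in list(list(east, 90), list(south, 180), list(west, 270),
                    list(north, 0))) {
    a <- cell_aspect(pair[[1]])
    inner <- a[2:(n - 1), 2:(n - 1)]
    expect_true(all(abs(inner - pair[[2]]) < 1e-9))
  }
  flat <- bathymetry_grid(matrix(7, n, n))
  expect_true(all(is.na(cell_aspect(flat))))
})

test_that("cell aspect matches a hand-computed Horn gradient on a saddle", {
  n <- 15
  xs <- seq_len(n); ys <- seq_len(n)
  depth <- outer(ys, xs, function(r, c) 10 + 0.05 * (c - 8)^2 - 0.03 * (r - 8)^2)
  g <- bathymetry_grid(depth)
  a <- cell_aspect(g)
  z <- -depth
  for (cell in list(c(5, 5), c(8, 11), c(12, 4), c(3, 12))) {
    expect_equal(a[cell[1], cell[2]],
                 oracle_horn_aspect(z, cell[1], cell[2]),
                 tolerance = 1e-9)
  }
})

test_that("rotating the grid 90 degrees rotates aspects and classes", {
  set.seed(7)
  n <- 20
  depth <- 10 + matrix(cumsum(rnorm(n * n, sd = 0.1)), n, n)
  depth <- (depth + t(depth)) / 2  # smooth-ish random surface
  g <- bathymetry_grid(depth)
  a <- cell_aspect(g)
  rot_cw <- function(m) t(m[nrow(m):1, ])
  a_rot <- cell_aspect(bathymetry_grid(rot_cw(depth)))
  for (r in 2:(n - 1)) {
    for (cl in 2:(n - 1)) {
      got <- a_rot[cl, n + 1 - r]
      want <- (a[r, cl] + 90) %% 360
      if (is.na(a[r, cl])) {
        expect_true(is.na(got))
      } else {
        expect_equal(got, want, tolerance = 1e-9)
      }
    }
  }
  cls <- classify_aspect(a[!is.na(a)])
  cls_rot <- classify_aspect((a[!is.na(a)] + 90) %% 360)
  perm <- c(N = "E", E = "S", S = "W", W = "N")
  expect_equal(unname(perm[cls]), cls_rot)
})

test_that("circular mean aspect behaves like a vector mean", {
  expect_equal(mean_aspect(c(350, 10)), 0)
  expect_equal(mean_aspect(90), 90)
  expect_equal(mean_aspect(c(0, 90)), 45)
  expect_true(is.na(mean_aspect(c(NA_real_, NA_real_))))
  # singleton identity and shift equivariance on random sets
  set.seed(31)
  for (i in 1:20) {
    x <- runif(sample(2:8, 1), 0, 360)
    theta <- runif(1, 0, 360)
    expect_equal(mean_aspect((x + theta) %% 360),
                 (mean_aspect(x) + theta) %% 360, tolerance = 1e-9)
  }
  expect_equal(mean_aspect(123.4), 123.4)
})

test_that("aspect classes use half-open 45-degree-centred quadrants", {
  expect_equal(classify_aspect(0), "N")
  expect_equal(classify_aspect(315), "N")  # W is [225, 315): 315 itself is N
  expect_equal(classify_aspect(c(134.9, 135)), c("E", "S"))
  expect_equal(classify_aspect(c(44.9, 45, 224.9, 225, 314.9)),
               c("N", "E", "S", "W", "W"))
})

test_that("profile extraction ties sampling, truncation and aspect together", {
  g <- make_reef_grid(reef_grid_spec(c(60, 60), "ribbon",
                                     crest_depth_m = 1.5,
                                     slope_base_depth_m = 25,
                                     slope_width_m = 300))
  axis <- cbind(c(350, 350), c(50, 550))  # along the slope, north-south
  lines <- make_transects(axis, spacing_m = 100, length_m = 400)
  res <- extract_profiles(g, lines)
  expect_gt(nrow(res$transects), 0)
  expect_true(all(res$profiles$depth_m > 2))
  expect_true(all(res$transects$aspect_class %in% c("N", "E", "S", "W")))
  # transects across a west-facing ribbon slope face west
  expect_true(all(res$transects$aspect_class == "W"))
})
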