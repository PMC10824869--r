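#' Define a transect line
#'
#' A straight sampling line across a reef slope, nominally 500 m long,
#' along which depths are sampled every 10 m.
#'
#' @param id Transect identifier.
#' @param start,end Numeric `(x, y)` endpoints in metres.
#' @param reef_id Optional reef assignment (NA if not yet assigned).
#' @return An object of class `transect_line`.
#' @export
transect_line <- function(id, start, end, reef_id = NA) {
  if (length(start) != 2 || length(end) != 2) {
    stop("start and end must be (x, y)", call. = FALSE)
  }
  len <- sqrt(sum((end - start)^2))
  if (len <= 0) stop("transect must have positive length", call. = FALSE)
  structure(list(id = id, reef_id = reef_id,
                 start = as.numeric(start), end = as.numeric(end),
                 length_m = len),
            class = "transect_line")
}

#' Generate transects as normals to an axis polyline
#'
#' Places transects at a fixed spacing along a reef-axis polyline,
#' each perpendicular to the local axis direction and centred on it — the
#' synthetic stand-in for centreline-based transect generation. Defaults
#' follow the sampling design: 500-m spacing, 500-m transects.
#'
#' @param axis Two-column matrix of `(x, y)` vertices of the axis polyline.
#' @param spacing_m Distance between successive transects along the axis.
#' @param length_m Transect length (centred on the axis).
#' @param id_prefix Prefix for generated transect ids.
#' @return List of [transect_line()] objects.
#' @export
make_transects <- function(axis, spacing_m = 500, length_m = 500,
                           id_prefix = "T") {
  axis <- as.matrix(axis)
  if (nrow(axis) < 2) stop("axis needs at least two vertices", call. = FALSE)
  seg <- diff(axis)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  stations <- seq(0, total, by = spacing_m)
  lines <- vector("list", length(stations))
  for (k in seq_along(stations)) {
    s <- stations[k]
    i <- max(which(cum <= s + 1e-9))
    i <- min(i, nrow(seg))
    frac <- (s - cum[i]) / seg_len[i]
    p <- axis[i, ] + frac * seg[i, ]
    u <- seg[i, ] / seg_len[i]
    n_vec <- c(-u[2], u[1])  # left-hand normal
    lines[[k]] <- transect_line(
      id = sprintf("%s%03d", id_prefix, k),
      start = p - n_vec * length_m / 2,
      end = p + n_vec * length_m / 2
    )
  }
  lines
}

# Bilinear interpolation of grid depths at arbitrary points; NA outside the
# hull of cell centres or when any contributing cell is nodata.
.interp_bilinear <- function(grid, x, y) {
  m <- grid$depth
  nr <- nrow(m); nc <- ncol(m); cell <- grid$cellsize
  cx <- (x - grid$xll) / cell + 0.5          # fractional column index
  ry <- nr + 0.5 - (y - grid$yll) / cell     # fractional row index (row 1 north)
  out <- rep(NA_real_, length(x))
  ok <- cx >= 1 & cx <= nc & ry >= 1 & ry <= nr
  if (!any(ok)) return(out)
  c0 <- pmin(pmax(floor(cx[ok]), 1), nc - 1); c1 <- c0 + 1
  r0 <- pmin(pmax(floor(ry[ok]), 1), nr - 1); r1 <- r0 + 1
  tx <- cx[ok] - c0; ty <- ry[ok] - r0
  v00 <- m[cbind(r0, c0)]; v01 <- m[cbind(r0, c1)]
  v10 <- m[cbind(r1, c0)]; v11 <- m[cbind(r1, c1)]
  out[ok] <- (1 - ty) * ((1 - tx) * v00 + tx * v01) +
    ty * ((1 - tx) * v10 + tx * v11)
  out
}

#' Sample a depth profile along a transect
#'
#' Bilinearly interpolates grid depths at 10-m steps from the transect's
#' start point. Nodata cells (and points outside the grid) propagate as NA.
#'
#' @param grid A [bathymetry_grid()].
#' @param line A [transect_line()].
#' @param spacing_m Sample spacing along the line (default 10 m).
#' @return Numeric depth vector with attribute `distance_m`; errors if the
#'   line yields no finite samples at all.
#' @export
sample_profile <- function(grid, line, spacing_m = 10) {
  stopifnot(inherits(grid, "bathymetry_grid"), inherits(line, "transect_line"))
  d <- seq(0, line$length_m, by = spacing_m)
  u <- (line$end - line$start) / line$length_m
  x <- line$start[1] + u[1] * d
  y <- line$start[2] + u[2] * d
  depths <- .interp_bilinear(grid, x, y)
  if (all(is.na(depths))) {
    stop("transect '", line$id, "' lies wholly outside the grid", call. = FALSE)
  }
  attr(depths, "distance_m") <- d
  depths
}

#' Truncate a profile at the shallow-depth limit
#'
#' Strips from both ends every leading and trailing point with depth at or
#' above the truncation limit (<= 2 m by default, i.e. on or near the reef
#' crest/flat). Interior shallow points are retained: only the ends are
#' truncated.
#'
#' @param depths Numeric depth vector (positive-down m).
#' @param limit_m Truncation depth (default 2 m).
#' @return The retained depths (possibly length 0), with attributes
#'   `kept` (index range into the input) and `fully_truncated` (logical).
#' @export
truncate_profile <- function(depths, limit_m = 2) {
  if (length(depths) == 0) stop("empty profile", call. = FALSE)
  deep_enough <- !is.na(depths) & depths > limit_m
  if (!any(deep_enough)) {
    out <- numeric(0)
    attr(out, "kept") <- integer(0)
    attr(out, "fully_truncated") <- TRUE
    return(out)
  }
  i0 <- which(deep_enough)[1]
  i1 <- which(deep_enough)[sum(deep_enough)]
  out <- as.numeric(depths[i0:i1])
  attr(out, "kept") <- i0:i1
  attr(out, "fully_truncated") <- FALSE
  out
}

# ---- planar geometry helpers (no spatial package dependency) ---------------

point_in_polygon <- function(pt, ring) {
  # even-odd ray casting; ring is a closed or open two-column matrix
  x <- pt[1]; y <- pt[2]
  rx <- ring[, 1]; ry <- ring[, 2]
  n <- length(rx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((ry[i] > y) != (ry[j] > y)) &&
        (x < (rx[j] - rx[i]) * (y - ry[i]) / (ry[j] - ry[i]) + rx[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

dist_point_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((a + t * ab - p)^2))
}

segments_intersect <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  (o1 != o2 && o3 != o4) ||
    (o1 == 0 && dist_point_segment(q1, p1, p2) == 0) ||
    (o2 == 0 && dist_point_segment(q2, p1, p2) == 0) ||
    (o3 == 0 && dist_point_segment(p1, q1, q2) == 0) ||
    (o4 == 0 && dist_point_segment(p2, q1, q2) == 0)
}

dist_segment_segment <- function(p1, p2, q1, q2) {
  if (segments_intersect(p1, p2, q1, q2)) return(0)
  min(dist_point_segment(p1, q1, q2), dist_point_segment(p2, q1, q2),
      dist_point_segment(q1, p1, p2), dist_point_segment(q2, p1, p2))
}

# Distance from a transect segment to a polygon (0 if touching or inside).
dist_line_polygon <- function(start, end, ring) {
  if (point_in_polygon(start, ring) || point_in_polygon(end, ring)) return(0)
  n <- nrow(ring)
  d <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- min(d, dist_segment_segment(start, end, ring[i, ], ring[j, ]))
    if (d == 0) break
  }
  d
}

#' Assign a transect to its nearest reef polygon
#'
#' Finds the reef polygon nearest to the transect line (distance to the
#' polygon boundary, 0 if the transect touches or lies inside) and assigns
#' the transect to it when the distance is within the search radius
#' (1000 m by default). Beyond the radius the transect stays unassigned.
#'
#' @param line A [transect_line()].
#' @param reef_polygons Named list of two-column coordinate matrices (one
#'   ring per reef).
#' @param max_dist_m Search radius in metres.
#' @return The reef id (name), or `NA_character_` if unassigned.
#' @export
assign_reef <- function(line, reef_polygons, max_dist_m = 1000) {
  stopifnot(inherits(line, "transect_line"))
  if (length(reef_polygons) == 0) return(NA_character_)
  ids <- names(reef_polygons)
  if (is.null(ids)) ids <- as.character(seq_along(reef_polygons))
  d <- vapply(reef_polygons, function(ring) {
    dist_line_polygon(line$start, line$end, as.matrix(ring))
  }, numeric(1))
  best <- which.min(d)
  if (d[best] <= max_dist_m) ids[best] else NA_character_
}

# ---- circular aspect statistics --------------------------------------------

#' Circular mean of aspect angles
#'
#' Vector (circular) mean: `[360 + atan2(s, c) * 180/pi] mod 360` where `s`
#' and `c` are the means of the sines and cosines of the aspects. Undefined
#' aspects (NA) are dropped; an all-NA input (or a resultant of zero length,
#' e.g. two opposite aspects) returns NA.
#'
#' @param aspect_deg Aspect angles in degrees clockwise from north.
#' @return Mean aspect in `[0, 360)`, or NA if undefined.
#' @examples
#' mean_aspect(c(350, 10))  # 0, not the arithmetic 180
#' @export
mean_aspect <- function(aspect_deg) {
  a <- aspect_deg[!is.na(aspect_deg)]
  if (length(a) == 0) return(NA_real_)
  rad <- a * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  if (sqrt(s^2 + c^2) < 1e-9) return(NA_real_)
  (360 + atan2(s, c) * 180 / pi) %% 360
}

#' Classify a mean aspect into N/E/S/W
#'
#' Quadrants are centred on the cardinal directions with half-open
#' boundaries: N = `[315,360) U [0,45)`, E = `[45,135)`, S = `[135,225)`,
#' W = `[225,315)`.
#'
#' @param aspect_deg Aspect(s) in degrees; NA gives NA.
#' @return Character vector of `"N"`, `"E"`, `"S"`, `"W"`.
#' @export
classify_aspect <- function(aspect_deg) {
  a <- aspect_deg %% 360
  out <- rep(NA_character_, length(a))
  out[!is.na(a) & (a >= 315 | a < 45)] <- "N"
  out[!is.na(a) & a >= 45 & a < 135] <- "E"
  out[!is.na(a) & a >= 135 & a < 225] <- "S"
  out[!is.na(a) & a >= 225 & a < 315] <- "W"
  out
}

#' Mean aspect of the cells around a transect
#'
#' Averages (circularly) the per-cell aspects of every grid cell whose
#' centre lies within `buffer_m` of the transect line segment.
#'
#' @param grid A [bathymetry_grid()].
#' @param line A [transect_line()].
#' @param aspect Optional precomputed [cell_aspect()] matrix for `grid`.
#' @param buffer_m Buffer radius in metres (default 10).
#' @return Mean aspect in degrees, or NA if no defined aspect falls in the
#'   buffer.
#' @export
transect_mean_aspect <- function(grid, line, aspect = NULL, buffer_m = 10) {
  if (is.null(aspect)) aspect <- cell_aspect(grid)
  xs <- grid_x(grid); ys <- grid_y(grid)
  # bounding box prefilter, then exact point-segment distance
  xmin <- min(line$start[1], line$end[1]) - buffer_m
  xmax <- max(line$start[1], line$end[1]) + buffer_m
  ymin <- min(line$start[2], line$end[2]) - buffer_m
  ymax <- max(line$start[2], line$end[2]) + buffer_m
  cols <- which(xs >= xmin & xs <= xmax)
  rows <- which(ys >= ymin & ys <= ymax)
  vals <- c()
  for (r in rows) {
    for (cl in cols) {
      if (is.na(aspect[r, cl])) next
      if (dist_point_segment(c(xs[cl], ys[r]), line$start, line$end) <=
          buffer_m) {
        vals <- c(vals, aspect[r, cl])
      }
    }
  }
  mean_aspect(vals)
}

#' Extract truncated transect profiles from a grid
#'
#' Runs the full sampling stage for a set of transect lines: bilinear depth
#' sampling at 10-m steps, end truncation at the shallow limit, reef
#' assignment (optional), and per-transect mean aspect and aspect class.
#' Transects that are fully truncated or retain fewer than 2 points are
#' dropped.
#'
#' @param grid A [bathymetry_grid()].
#' @param lines List of [transect_line()] objects.
#' @param reef_polygons Optional named list of polygon rings for
#'   [assign_reef()].
#' @param truncate_limit_m Shallow truncation depth (default 2 m).
#' @return List with `profiles` (data.frame: transect_id, reef_id,
#'   distance_m, depth_m) and `transects` (data.frame: transect_id, reef_id,
#'   n_points, mean_aspect_deg, aspect_class).
#' @export
extract_profiles <- function(grid, lines, reef_polygons = NULL,
                             truncate_limit_m = 2) {
  aspect <- cell_aspect(grid)
  prof_list <- list()
  meta_list <- list()
  for (line in lines) {
    depths <- tryCatch(sample_profile(grid, line), error = function(e) NULL)
    if (is.null(depths)) next
    kept <- truncate_profile(depths, truncate_limit_m)
    if (attr(kept, "fully_truncated") || length(kept) < 2) next
    reef <- if (!is.null(reef_polygons)) {
      assign_reef(line, reef_polygons)
    } else {
      line$reef_id
    }
    ma <- transect_mean_aspect(grid, line, aspect = aspect)
    dist0 <- attr(depths, "distance_m")[attr(kept, "kept")]
    prof_list[[length(prof_list) + 1]] <- data.frame(
      transect_id = line$id, reef_id = reef,
      distance_m = dist0 - dist0[1], depth_m = as.numeric(kept)
    )
    meta_list[[length(meta_list) + 1]] <- data.frame(
      transect_id = line$id, reef_id = reef, n_points = length(kept),
      mean_aspect_deg = ma, aspect_class = classify_aspect(ma)
    )
  }
  list(
    profiles = do.call(rbind, prof_list),
    transects = do.call(rbind, meta_list)
  )
}
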