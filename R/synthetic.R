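#' @importFrom stats rnorm rbeta runif rbinom plogis qlogis kmeans pnorm
#'   dbeta optim sd
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Describe one terrain segment of a synthetic profile
#'
#' @param kind One of `"flat"`, `"ramp"`, `"depression"`, `"dropoff"`,
#'   `"high"`. Ramps and drop-offs deepen by `relief_m` over the segment;
#'   depressions dip `relief_m` below the entry level and return; highs rise
#'   `relief_m` above it and return; flats keep the entry level.
#' @param length_m Along-track length in metres; must be a positive multiple
#'   of the 10-m sampling interval.
#' @param relief_m Vertical relief of the segment in metres (0 for flats).
#' @return A list describing the segment, for use in [terrain_spec()].
#' @export
segment <- function(kind = c("flat", "ramp", "depression", "dropoff", "high"),
                    length_m, relief_m = 0) {
  kind <- match.arg(kind)
  if (!is.finite(length_m) || length_m <= 0 || length_m %% 10 != 0) {
    stop("segment length_m must be a positive multiple of 10 m", call. = FALSE)
  }
  if (!is.finite(relief_m) || relief_m < 0) {
    stop("segment relief_m must be >= 0", call. = FALSE)
  }
  if (kind %in% c("depression", "dropoff", "high") && relief_m == 0) {
    stop("kind '", kind, "' requires relief_m > 0", call. = FALSE)
  }
  list(kind = kind, length_m = length_m, relief_m = relief_m)
}

#' Specification of a synthetic 1-D terrain profile
#'
#' Defines an ordered sequence of terrain segments laid out at 10-m sample
#' spacing with a common base depth. Depths are positive-down metres
#' ("depth 12" means 12 m below the sea surface). The generated profile is a
#' pure function of the spec, including its seed.
#'
#' @param segments List of segments from [segment()]; at least one.
#' @param base_depth_m Starting depth in metres (> 0, positive-down).
#' @param noise_sd_m Standard deviation of additive Gaussian depth noise in
#'   metres (0 disables noise; noisy depths are kept > 0).
#' @param seed Integer seed controlling the noise realisation.
#' @return An object of class `terrain_spec`.
#' @examples
#' sp <- terrain_spec(list(segment("flat", 500)), base_depth_m = 12)
#' make_profile(sp)
#' @export
terrain_spec <- function(segments, base_depth_m, noise_sd_m = 0, seed = 1L) {
  if (!is.list(segments) || length(segments) == 0) {
    stop("terrain_spec requires at least one segment", call. = FALSE)
  }
  ok <- vapply(segments, function(s) {
    is.list(s) && all(c("kind", "length_m", "relief_m") %in% names(s))
  }, logical(1))
  if (!all(ok)) stop("segments must be built with segment()", call. = FALSE)
  if (!is.finite(base_depth_m) || base_depth_m <= 0) {
    stop("base_depth_m must be > 0 (positive-down metres)", call. = FALSE)
  }
  if (!is.finite(noise_sd_m) || noise_sd_m < 0) {
    stop("noise_sd_m must be >= 0", call. = FALSE)
  }
  structure(
    list(segments = segments, base_depth_m = base_depth_m,
         noise_sd_m = noise_sd_m, seed = as.integer(seed)),
    class = "terrain_spec"
  )
}

# Triangular bump over n samples: rises to exactly `relief` then returns to 0
# at the segment's last sample.
.tri_bump <- function(n, relief) {
  p <- ceiling(n / 2)
  up <- relief * seq_len(p) / p
  down <- if (n > p) relief * (seq.int(n - p - 1, 0) / (n - p)) else numeric(0)
  c(up, down)
}

#' Generate a depth profile from a terrain specification
#'
#' Lays the segments end to end at 10-m spacing, starting with a single point
#' at the base depth. Each segment realises its declared relief exactly
#' before noise: a depression of relief r contains a point exactly r deeper
#' than its entry level, a high a point exactly r shallower, and ramps and
#' drop-offs end exactly r deeper than they start.
#'
#' @param spec A [terrain_spec()].
#' @return Numeric vector of depths (positive-down metres) at 10-m spacing,
#'   with attribute `distance_m` giving along-track distances.
#' @export
make_profile <- function(spec) {
  stopifnot(inherits(spec, "terrain_spec"))
  cur <- spec$base_depth_m
  depths <- cur
  for (s in spec$segments) {
    n <- as.integer(s$length_m / 10)
    piece <- switch(
      s$kind,
      flat = rep(cur, n),
      ramp = cur + s$relief_m * seq_len(n) / n,
      dropoff = cur + s$relief_m * seq_len(n) / n,
      depression = cur + .tri_bump(n, s$relief_m),
      high = cur - .tri_bump(n, s$relief_m)
    )
    cur <- piece[n]
    depths <- c(depths, piece)
  }
  if (any(depths <= 0)) {
    stop("profile rises above sea level; increase base_depth_m or reduce ",
         "relief of 'high' segments", call. = FALSE)
  }
  if (spec$noise_sd_m > 0) {
    depths <- with_seed(spec$seed, {
      noisy <- depths + rnorm(length(depths), sd = spec$noise_sd_m)
      pmax(noisy, 0.01)  # truncate so depths stay below the surface
    })
  }
  attr(depths, "distance_m") <- (seq_along(depths) - 1) * 10
  depths
}

#' Specification of a small synthetic reef bathymetry grid
#'
#' Describes an idealised reef surface on a regular 10-m grid: either an
#' annular platform (shallow crest ring with a gentle lagoon inside and a
#' monotone outer slope) or a ribbon reef (north-south crest line with a
#' west-facing slope). Used to exercise transect sampling and aspect
#' computations on surfaces with known geometry.
#'
#' @param shape Integer `(rows, cols)` of 10-m cells.
#' @param geometry `"annular_platform"` or `"ribbon"`.
#' @param crest_depth_m Depth of the reef crest (m, positive-down).
#' @param slope_base_depth_m Depth reached at the foot of the slope (m);
#'   must exceed `crest_depth_m`.
#' @param slope_width_m Horizontal width of the slope in metres.
#' @param noise_sd_m Additive Gaussian depth noise (m); 0 disables.
#' @param seed Integer seed for the noise realisation.
#' @return An object of class `reef_grid_spec`.
#' @export
reef_grid_spec <- function(shape, geometry = c("annular_platform", "ribbon"),
                           crest_depth_m = 1.5, slope_base_depth_m = 25,
                           slope_width_m = 300, noise_sd_m = 0, seed = 1L) {
  geometry <- match.arg(geometry)
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 3)) {
    stop("shape must be (rows, cols) with both >= 3", call. = FALSE)
  }
  if (crest_depth_m <= 0 || slope_base_depth_m <= 0) {
    stop("depths must be positive-down (> 0)", call. = FALSE)
  }
  if (crest_depth_m >= slope_base_depth_m) {
    stop("crest_depth_m must be shallower than slope_base_depth_m",
         call. = FALSE)
  }
  need_cells <- ceiling(slope_width_m / 10) + 4
  if (geometry == "annular_platform" && min(shape) < 2 * need_cells) {
    stop("grid too small to contain the annular platform; need at least ",
         2 * need_cells, " cells on each side", call. = FALSE)
  }
  if (geometry == "ribbon" && shape[2] < need_cells) {
    stop("grid too narrow for the ribbon slope; need at least ", need_cells,
         " columns", call. = FALSE)
  }
  structure(
    list(shape = shape, geometry = geometry, crest_depth_m = crest_depth_m,
         slope_base_depth_m = slope_base_depth_m,
         slope_width_m = slope_width_m, noise_sd_m = noise_sd_m,
         seed = as.integer(seed)),
    class = "reef_grid_spec"
  )
}

#' Generate a bathymetry grid from a reef specification
#'
#' @param spec A [reef_grid_spec()].
#' @return A [bathymetry_grid()] with 10-m cells, row 1 northernmost.
#' @export
make_reef_grid <- function(spec) {
  stopifnot(inherits(spec, "reef_grid_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  cell <- 10
  crest <- spec$crest_depth_m
  base <- spec$slope_base_depth_m
  sw <- spec$slope_width_m

  if (spec$geometry == "annular_platform") {
    # Crest ring at a fixed radius; outward the depth ramps to the slope
    # base, inward it eases down to a lagoon a few metres deeper than crest.
    cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
    r_crest <- (min(nr, nc) / 2 - sw / cell - 2) * cell
    lagoon <- min(crest + 5, (crest + base) / 2)
    lagoon_w <- max(r_crest / 2, cell)
    row_i <- matrix(seq_len(nr), nr, nc)
    col_i <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    r <- sqrt(((col_i - cx) * cell)^2 + ((row_i - cy) * cell)^2)
    depth <- matrix(base, nr, nc)
    out <- r >= r_crest
    depth[out] <- crest + (base - crest) * pmin((r[out] - r_crest) / sw, 1)
    inn <- r < r_crest
    depth[inn] <- lagoon - (lagoon - crest) *
      pmax(1 - (r_crest - r[inn]) / lagoon_w, 0)
  } else {
    # Ribbon: crest column near the eastern edge, slope deepening westward.
    x_crest <- nc - 2
    col_i <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    west <- pmax((x_crest - col_i) * cell, 0)
    depth <- crest + (base - crest) * pmin(west / sw, 1)
  }

  if (spec$noise_sd_m > 0) {
    depth <- with_seed(spec$seed, {
      pmax(depth + rnorm(length(depth), sd = spec$noise_sd_m), 0.01)
    })
  }
  bathymetry_grid(depth, xll = 0, yll = 0, cellsize = cell)
}

#' Specification of a two-component beta-mixture proportion dataset
#'
#' Observations carry a depth class (shallow/deep) and an aspect class
#' (N/E/S/W). Each is drawn from mixture component 1 with probability `pi1`
#' and otherwise from component 2; the response is Beta-distributed with a
#' logit-linked mean depending on the covariates and a per-component
#' precision.
#'
#' @param n_obs Number of observations.
#' @param pi1 Mixing weight of component 1, in (0,1) (1 allowed for the
#'   degenerate single-component case used in tests).
#' @param beta1,beta2 Coefficient vectors (intercept, deep, E, S, W) on the
#'   logit scale for components 1 and 2.
#' @param phi Length-2 vector of positive beta precisions.
#' @param seed Integer seed.
#' @return An object of class `mixture_sim_spec`.
#' @export
mixture_sim_spec <- function(n_obs, pi1, beta1, beta2, phi, seed = 1L) {
  if (!is.finite(pi1) || pi1 <= 0 || pi1 > 1) {
    stop("pi1 must lie in (0, 1]", call. = FALSE)
  }
  if (length(phi) != 2 || any(phi <= 0)) {
    stop("phi must be two positive precisions", call. = FALSE)
  }
  if (length(beta1) != 5 || length(beta2) != 5) {
    stop("beta1 and beta2 must have 5 coefficients ",
         "(intercept, deep, E, S, W)", call. = FALSE)
  }
  if (n_obs < 1) stop("n_obs must be >= 1", call. = FALSE)
  structure(
    list(n_obs = as.integer(n_obs), pi1 = pi1, beta1 = beta1, beta2 = beta2,
         phi = phi, seed = as.integer(seed)),
    class = "mixture_sim_spec"
  )
}

# Dummy-coded design matrix with references shallow / N.
mixture_design <- function(depth_class, aspect_class, interaction = FALSE) {
  deep <- as.numeric(depth_class == "deep")
  E <- as.numeric(aspect_class == "E")
  S <- as.numeric(aspect_class == "S")
  W <- as.numeric(aspect_class == "W")
  X <- cbind(intercept = 1, deep = deep, E = E, S = S, W = W)
  if (interaction) {
    X <- cbind(X, `deep:E` = deep * E, `deep:S` = deep * S,
               `deep:W` = deep * W)
  }
  X
}

#' Simulate proportion data from a two-component beta-regression mixture
#'
#' @param spec A [mixture_sim_spec()].
#' @return A data.frame with columns `proportion` (in (0,1)), `depth_class`,
#'   `aspect_class` and `true_component`.
#' @export
simulate_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_obs
    depth_class <- sample(c("shallow", "deep"), n, replace = TRUE)
    aspect_class <- sample(c("N", "E", "S", "W"), n, replace = TRUE)
    comp <- ifelse(runif(n) < spec$pi1, 1L, 2L)
    X <- mixture_design(depth_class, aspect_class)
    eta <- ifelse(comp == 1L, X %*% spec$beta1, X %*% spec$beta2)
    mu <- plogis(eta)
    phi <- spec$phi[comp]
    y <- rbeta(n, mu * phi, (1 - mu) * phi)
    eps <- 1e-12
    y <- pmin(pmax(y, eps), 1 - eps)
    data.frame(proportion = y, depth_class = depth_class,
               aspect_class = aspect_class, true_component = comp)
  })
}
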