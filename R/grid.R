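#' Gridded bathymetry container
#'
#' Depths on a regular grid of 10-m cells, positive-down metres. Row 1 is the
#' northernmost row (the usual raster layout); cell centres are at
#' `xll + (col - 0.5) * cellsize` and `yll + (nrow - row + 0.5) * cellsize`.
#'
#' @param depth Numeric matrix of depths (NA = nodata).
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param cellsize Cell size in metres; fixed at 10 m, the resolution of the
#'   satellite-derived bathymetry the pipeline is designed for.
#' @return An object of class `bathymetry_grid`.
#' @export
bathymetry_grid <- function(depth, xll = 0, yll = 0, cellsize = 10) {
  if (!is.matrix(depth)) stop("depth must be a matrix", call. = FALSE)
  if (cellsize != 10) {
    stop("cell size is fixed at 10 m for this pipeline", call. = FALSE)
  }
  structure(
    list(depth = depth, xll = xll, yll = yll, cellsize = cellsize),
    class = "bathymetry_grid"
  )
}

#' @export
print.bathymetry_grid <- function(x, ...) {
  cat(sprintf("Bathymetry grid: %d x %d cells at %g m, origin (%g, %g)\n",
              nrow(x$depth), ncol(x$depth), x$cellsize, x$xll, x$yll))
  rng <- range(x$depth, na.rm = TRUE)
  cat(sprintf("  depth range %.2f - %.2f m (positive-down), %d nodata cells\n",
              rng[1], rng[2], sum(is.na(x$depth))))
  invisible(x)
}

# x/y coordinates of cell centres.
grid_x <- function(grid) grid$xll + (seq_len(ncol(grid$depth)) - 0.5) * grid$cellsize
grid_y <- function(grid) grid$yll + (nrow(grid$depth) - seq_len(nrow(grid$depth)) + 0.5) * grid$cellsize

#' Read bathymetry from an ESRI ASCII grid
#'
#' Parses the plain-text ESRI ASCII raster format (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header followed by rows
#' north to south). Files conventionally store elevation, negative below sea
#' level; with `convention = "elevation"` (the default) values are negated
#' into the package's positive-down depths at the I/O boundary.
#'
#' @param path Path to the `.asc` file.
#' @param convention `"elevation"` (negate on read) or `"depth"` (use as-is).
#' @return A [bathymetry_grid()].
#' @export
read_bathymetry_asc <- function(path, convention = c("elevation", "depth")) {
  convention <- match.arg(convention)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[key]])) {
      stop("ESRI ASCII header missing '", key, "' in ", path, call. = FALSE)
    }
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ESRI ASCII body has ", length(vals), " values; expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  if (convention == "elevation") m <- -m
  bathymetry_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
                  cellsize = hdr$cellsize)
}

#' Write bathymetry to an ESRI ASCII grid
#'
#' Inverse of [read_bathymetry_asc()]; with `convention = "elevation"` the
#' stored values are negated depths (negative below sea level).
#'
#' @param grid A [bathymetry_grid()].
#' @param path Output path.
#' @param convention `"elevation"` or `"depth"`.
#' @param nodata Value written for NA cells.
#' @return `path`, invisibly.
#' @export
write_bathymetry_asc <- function(grid, path,
                                 convention = c("elevation", "depth"),
                                 nodata = -9999) {
  convention <- match.arg(convention)
  m <- grid$depth
  if (convention == "elevation") m <- -m
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.6f", grid$xll),
    sprintf("yllcorner %.6f", grid$yll),
    sprintf("cellsize %.6f", grid$cellsize),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Per-cell downslope aspect (Horn's method)
#'
#' Computes, for every interior cell, the compass direction the slope faces
#' (degrees clockwise from north) using Horn's 3x3 finite-difference gradient
#' on elevation (negated depth) — the estimator behind the standard GIS
#' Aspect tool. Flat cells (zero gradient) are undefined (NA), as are cells
#' whose 3x3 neighbourhood contains nodata. Border cells are NA.
#'
#' @param grid A [bathymetry_grid()].
#' @return Matrix of aspects in `[0, 360)` degrees, NA where undefined.
#' @export
cell_aspect <- function(grid) {
  stopifnot(inherits(grid, "bathymetry_grid"))
  z <- -grid$depth  # elevation, increasing upward
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("grid must be at least 3x3", call. = FALSE)
  out <- matrix(NA_real_, nr, nc)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  # 3x3 neighbours: rows run north->south, so row-1 is the northern neighbour
  a <- z[ri - 1, ci - 1]; b <- z[ri - 1, ci]; cc <- z[ri - 1, ci + 1]
  d <- z[ri, ci - 1];                          f <- z[ri, ci + 1]
  g <- z[ri + 1, ci - 1]; h <- z[ri + 1, ci]; i2 <- z[ri + 1, ci + 1]
  cell <- grid$cellsize
  dzdx <- ((cc + 2 * f + i2) - (a + 2 * d + g)) / (8 * cell)   # east
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i2)) / (8 * cell)   # north
  flat <- abs(dzdx) < 1e-12 & abs(dzdy) < 1e-12
  asp <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360  # bearing of downslope vector
  asp[flat] <- NA_real_
  out[ri, ci] <- asp
  out
}
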