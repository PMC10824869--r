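#' Read reef polygons from GeoJSON
#'
#' Reads a FeatureCollection of Polygon features; each feature's
#' `properties$reef_id` (or `id`) names the reef. Only the outer ring is
#' used. Coordinates are assumed to be in the same projected metre units as
#' the bathymetry grid.
#'
#' @param path GeoJSON file path.
#' @return Named list of two-column coordinate matrices.
#' @export
read_reef_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a FeatureCollection: ", path,
                                 call. = FALSE)
  out <- list()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "Polygon")) next
    id <- f$properties$reef_id %||% f$properties$id %||% f$id
    if (is.null(id)) stop("polygon feature without reef_id in ", path,
                          call. = FALSE)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    out[[as.character(id)]] <- ring
  }
  if (length(out) == 0) stop("no Polygon features in ", path, call. = FALSE)
  out
}

#' Read transect lines from GeoJSON
#'
#' Reads LineString features with an `id` property (two-point lines).
#'
#' @param path GeoJSON file path.
#' @return List of [transect_line()] objects.
#' @export
read_transect_lines <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a FeatureCollection: ", path,
                                 call. = FALSE)
  out <- list()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "LineString")) next
    id <- f$properties$id %||% f$id
    if (is.null(id)) stop("LineString feature without id in ", path,
                          call. = FALSE)
    co <- f$geometry$coordinates
    start <- c(co[[1]][[1]], co[[1]][[2]])
    last <- co[[length(co)]]
    end <- c(last[[1]], last[[2]])
    out[[length(out) + 1]] <- transect_line(as.character(id), start, end,
                                            reef_id = f$properties$reef_id %||% NA)
  }
  if (length(out) == 0) stop("no LineString features in ", path, call. = FALSE)
  out
}

#' Write reef susceptibility as GeoJSON
#'
#' Joins reef polygons to their percentage of transects exceeding a
#' threshold, for mapping.
#'
#' @param reef_polygons Named list of polygon rings.
#' @param susceptibility Output of [reef_susceptibility()].
#' @param threshold Threshold to map.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_susceptibility_geojson <- function(reef_polygons, susceptibility,
                                         threshold, path) {
  sub <- susceptibility[susceptibility$threshold == threshold, ]
  feats <- lapply(names(reef_polygons), function(id) {
    ring <- reef_polygons[[id]]
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    pct <- sub$pct_exceeding[match(id, sub$reef_id)]
    list(
      type = "Feature",
      properties = list(reef_id = id, threshold = threshold,
                        pct_exceeding = if (is.na(pct)) NULL else pct),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ])))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
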