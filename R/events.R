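#' Construct an EID event record
#'
#' One emergence event: the documented first appearance of a wildlife-origin
#' pathogen in people, located by a spatial footprint whose precision ranges
#' from a 5 km buffer around exact coordinates to a country-sized polygon.
#' The footprint is precomputed once as the set of candidate grid cells and
#' never re-derived during resampling.
#'
#' @param id event identifier.
#' @param year calendar year of emergence (1940-2008).
#' @param footprint integer vector of candidate grid-cell indices (must
#'   intersect the land mask).
#' @param precise `TRUE` if the event was geocoded to exact coordinates
#'   (single-cell footprint at this resolution).
#' @param category event class label; the study models `"wildlife_zoonosis"`.
#' @return An object of class `eid_event`.
#' @export
eid_event <- function(id, year, footprint, precise = length(footprint) == 1L,
                      category = "wildlife_zoonosis") {
  year <- as.integer(year)
  stopifnot(year >= 1940L, year <= 2008L)
  footprint <- as.integer(footprint)
  if (length(footprint) == 0L)
    stop(sprintf("event '%s' has an empty footprint", id))
  structure(list(id = as.character(id), year = year,
                 footprint = sort(unique(footprint)),
                 precise = isTRUE(precise), category = category),
            class = "eid_event")
}

#' Circular buffer polygon around a point
#'
#' Approximates a geodesic circle of radius `radius_km` by a planar small
#' circle in degree space (metres-per-degree evaluated at the point's
#' latitude). Adequate for the 5 km location buffers used for precisely
#' geocoded events, which are two orders of magnitude smaller than a grid
#' cell.
#'
#' @param lon,lat centre in degrees.
#' @param radius_km buffer radius (default 5).
#' @param n_vertices polygon resolution.
#' @return A two-column matrix of (lon, lat) vertices, closed ring implied.
#' @export
buffer_point <- function(lon, lat, radius_km = 5, n_vertices = 32L) {
  stopifnot(radius_km >= 0)
  km_per_deg_lat <- 6371 * pi / 180
  km_per_deg_lon <- km_per_deg_lat * cos(lat * pi / 180)
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  if (radius_km == 0 || km_per_deg_lon <= 0) {
    # degenerate: the point itself (about-1m square so rasterisation works)
    eps <- 1e-5
    return(cbind(lon = lon + c(-eps, eps, eps, -eps),
                 lat = lat + c(-eps, -eps, eps, eps)))
  }
  cbind(lon = lon + (radius_km / km_per_deg_lon) * cos(t),
        lat = lat + (radius_km / km_per_deg_lat) * sin(t))
}

# Sutherland-Hodgman clip of a polygon (lon/lat vertex matrix) to an
# axis-aligned rectangle; returns the clipped vertex matrix (possibly 0 rows)
clip_poly_rect <- function(poly, xmin, xmax, ymin, ymax) {
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      prev <- pts[if (i == 1L) n else i - 1L, ]
      cin <- inside(cur); pin <- inside(prev)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, coord) {
    # intersection of segment p-q with the line coord = val
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  pts <- poly
  pts <- clip_edge(pts, function(p) p[1] >= xmin,
                   function(p, q) ix(p, q, xmin, 1))
  pts <- clip_edge(pts, function(p) p[1] <= xmax,
                   function(p, q) ix(p, q, xmax, 1))
  pts <- clip_edge(pts, function(p) p[2] >= ymin,
                   function(p, q) ix(p, q, ymin, 2))
  pts <- clip_edge(pts, function(p) p[2] <= ymax,
                   function(p, q) ix(p, q, ymax, 2))
  pts
}

# shoelace area (absolute), so vertex orientation is irrelevant
poly_area <- function(pts) {
  n <- nrow(pts)
  if (is.null(n) || n < 3L) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Rasterise an event polygon to its candidate grid cells
#'
#' Returns every land cell whose rectangle has a positive-area intersection
#' with the polygon (inclusive overlap, not centre containment), in
#' ascending cell-index order. Works for any simple polygon; multipolygons
#' are handled part by part.
#'
#' @param polygon a two-column (lon, lat) vertex matrix, or a list of such
#'   matrices (multipolygon parts).
#' @param grid a `grid_spec`.
#' @param event_id used in the error message when the polygon misses land.
#' @return Sorted integer vector of land-cell indices.
#' @export
polygon_to_cells <- function(polygon, grid, event_id = "?") {
  parts <- if (is.list(polygon) && !is.matrix(polygon)) polygon else list(polygon)
  hits <- integer(0)
  for (poly in parts) {
    stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
    # candidate cells from the bounding box only
    cmin <- max(1L, floor((min(poly[, 1]) + 180) / grid$dlon) + 1L)
    cmax <- min(grid$n_lon, floor((max(poly[, 1]) + 180 - 1e-12) / grid$dlon) + 1L)
    rmin <- max(1L, floor((min(poly[, 2]) + 90) / grid$dlat) + 1L)
    rmax <- min(grid$n_lat, floor((max(poly[, 2]) + 90 - 1e-12) / grid$dlat) + 1L)
    if (cmin > cmax || rmin > rmax) next
    for (r in rmin:rmax) {
      ymin <- -90 + (r - 1L) * grid$dlat; ymax <- ymin + grid$dlat
      for (cc in cmin:cmax) {
        xmin <- -180 + (cc - 1L) * grid$dlon; xmax <- xmin + grid$dlon
        clipped <- clip_poly_rect(poly, xmin, xmax, ymin, ymax)
        if (poly_area(clipped) > 1e-12)
          hits <- c(hits, (r - 1L) * grid$n_lon + cc)
      }
    }
  }
  hits <- sort(unique(hits))
  land <- hits[grid$land_mask[hits]]
  if (length(land) == 0L)
    stop(sprintf("event '%s': footprint polygon does not intersect land",
                 event_id))
  as.integer(land)
}

#' Apply the study filters to an event list
#'
#' Retains events at or after `min_year` (covariate availability starts in
#' 1970) in the modelled category, preserving input order. Warns rather than
#' errors on an empty result.
#'
#' @param events list of `eid_event`s.
#' @param min_year first retained year (default 1970).
#' @param category retained category (default `"wildlife_zoonosis"`).
#' @return Filtered list of `eid_event`s.
#' @export
filter_events <- function(events, min_year = 1970L,
                          category = "wildlife_zoonosis") {
  keep <- vapply(events, function(e) {
    e$year >= min_year && identical(e$category, category)
  }, logical(1))
  out <- events[keep]
  message(sprintf("filter_events: retained %d of %d events (year >= %d, %s)",
                  length(out), length(events), min_year, category))
  if (length(out) == 0L) warning("no events left after filtering")
  out
}

# ---- event IO ---------------------------------------------------------------

#' Read events from a GeoJSON FeatureCollection
#'
#' Features carry properties `id`, `year`, `category`, `precise` and a
#' `Point`, `Polygon` or `MultiPolygon` geometry. Points get a 5 km buffer;
#' footprints are rasterised to `grid` at read time.
#'
#' @param path GeoJSON file.
#' @param grid a `grid_spec`.
#' @return List of `eid_event`s.
#' @export
read_events_geojson <- function(path, grid) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(fc$type, "FeatureCollection"))
  lapply(fc$features, function(f) {
    p <- f$properties
    g <- f$geometry
    ring_to_matrix <- function(ring)
      do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    poly <- switch(g$type,
      Point = buffer_point(g$coordinates[[1]], g$coordinates[[2]]),
      Polygon = ring_to_matrix(g$coordinates[[1]]),  # outer ring only
      MultiPolygon = lapply(g$coordinates, function(pp) ring_to_matrix(pp[[1]])),
      stop(sprintf("unsupported geometry type '%s'", g$type)))
    cells <- polygon_to_cells(poly, grid, event_id = p$id)
    eid_event(p$id, p$year, cells,
              precise = isTRUE(p$precise) || identical(g$type, "Point"),
              category = if (is.null(p$category)) "wildlife_zoonosis"
                         else p$category)
  })
}

#' Write events to a GeoJSON FeatureCollection
#'
#' Footprints are written as MultiPolygon unions of cell rectangles (the
#' cached cell footprint, not the original source polygon); single-cell
#' precise events are written as cell-centre Points.
#'
#' @param events list of `eid_event`s.
#' @param grid their `grid_spec`.
#' @param path output path.
#' @export
write_events_geojson <- function(events, grid, path) {
  cell_rect <- function(i) {
    r <- (i - 1L) %/% grid$n_lon; cc <- (i - 1L) %% grid$n_lon
    xmin <- -180 + cc * grid$dlon; ymin <- -90 + r * grid$dlat
    list(list(list(xmin, ymin), list(xmin + grid$dlon, ymin),
              list(xmin + grid$dlon, ymin + grid$dlat),
              list(xmin, ymin + grid$dlat), list(xmin, ymin)))
  }
  feats <- lapply(events, function(e) {
    geom <- if (e$precise && length(e$footprint) == 1L) {
      i <- e$footprint
      list(type = "Point", coordinates = list(grid$lon[i], grid$lat[i]))
    } else {
      list(type = "MultiPolygon",
           coordinates = lapply(e$footprint, cell_rect))
    }
    list(type = "Feature",
         properties = list(id = e$id, year = e$year, category = e$category,
                           precise = e$precise),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read point events from CSV
#'
#' Columns `id, year, category, lon, lat`; each point receives a 5 km buffer
#' footprint.
#'
#' @param path CSV file.
#' @param grid a `grid_spec`.
#' @return List of `eid_event`s.
#' @export
read_events_csv <- function(path, grid) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    poly <- buffer_point(df$lon[i], df$lat[i])
    cells <- polygon_to_cells(poly, grid, event_id = df$id[i])
    eid_event(df$id[i], df$year[i], cells, precise = TRUE,
              category = df$category[i])
  })
}
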