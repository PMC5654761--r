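#' Define a global longitude-latitude analysis grid
#'
#' The study lattice is an equal-angle WGS84 grid covering the globe
#' (`n_lon` x `n_lat` cells, origin at lon -180 / lat -90). Cells are indexed
#' row-major from the south-west corner: index = (lat_row - 1) * n_lon +
#' lon_col. The canonical configuration is the 1-degree grid (360 x 180);
#' coarser grids (e.g. 40 x 20) are used for simulation studies.
#'
#' @param n_lon,n_lat number of cells in longitude / latitude. Must divide
#'   360 and 180 evenly.
#' @param land_mask logical vector of length `n_lon * n_lat`; `TRUE` marks a
#'   land cell. At least one cell must be land.
#' @return An object of class `grid_spec` with fields `n_lon`, `n_lat`,
#'   `dlon`, `dlat` (cell size in degrees), `land_mask`, `cell_area`
#'   (km^2, spherical band areas) and per-cell centre coordinates
#'   `lon`, `lat`.
#' @export
grid_spec <- function(n_lon = 360L, n_lat = 180L, land_mask = NULL) {
  n_lon <- as.integer(n_lon); n_lat <- as.integer(n_lat)
  stopifnot(n_lon >= 1L, n_lat >= 1L)
  dlon <- 360 / n_lon
  dlat <- 180 / n_lat
  n_cell <- n_lon * n_lat
  if (is.null(land_mask)) land_mask <- rep(TRUE, n_cell)
  stopifnot(is.logical(land_mask), length(land_mask) == n_cell)
  if (!any(land_mask)) stop("land_mask must contain at least one land cell")
  lat_bottom <- -90 + dlat * (seq_len(n_lat) - 1L)
  band_area <- band_area_km2(lat_bottom, lat_bottom + dlat, dlon)
  lon_centre <- -180 + dlon * (seq_len(n_lon) - 0.5)
  lat_centre <- lat_bottom + dlat / 2
  g <- list(
    n_lon = n_lon, n_lat = n_lat, dlon = dlon, dlat = dlat,
    land_mask = land_mask,
    cell_area = rep(band_area, each = n_lon),
    lon = rep(lon_centre, times = n_lat),
    lat = rep(lat_centre, each = n_lon)
  )
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells (%.3g deg), %d land cells (%.1f%%)\n",
              x$n_lon, x$n_lat, x$dlon, sum(x$land_mask),
              100 * mean(x$land_mask)))
  invisible(x)
}

n_cells <- function(grid) grid$n_lon * grid$n_lat

#' Spherical area of a grid band
#'
#' Area in km^2 of one cell in the latitude band `[lat_bottom, lat_top]`
#' with longitudinal width `dlon` degrees, on a sphere of radius 6371 km:
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))`. Depends only on the
#' latitude band, so cells in one row share an area.
#'
#' @param lat_bottom,lat_top band edges in degrees, `lat_top > lat_bottom`.
#' @param dlon cell width in degrees of longitude.
#' @return Area in km^2 (vectorised over bands).
#' @export
band_area_km2 <- function(lat_bottom, lat_top, dlon = 1) {
  stopifnot(all(lat_bottom >= -90), all(lat_top <= 90),
            all(lat_top > lat_bottom))
  R <- 6371
  R^2 * (dlon * pi / 180) *
    (sin(lat_top * pi / 180) - sin(lat_bottom * pi / 180))
}

#' Locate grid cells containing points
#'
#' @param grid a `grid_spec`.
#' @param lon,lat coordinates in degrees.
#' @return Integer cell indices (row-major from the south-west corner).
#'   Points on the +180 / +90 boundary are assigned to the last cell.
#' @export
cell_index <- function(grid, lon, lat) {
  col <- pmin(grid$n_lon, pmax(1L, floor((lon + 180) / grid$dlon) + 1L))
  row <- pmin(grid$n_lat, pmax(1L, floor((lat + 90) / grid$dlat) + 1L))
  as.integer((row - 1L) * grid$n_lon + col)
}

# ---- layers -----------------------------------------------------------------

#' Construct a gridded covariate layer
#'
#' A layer is one named surface on the study grid: static, tied to a decadal
#' snapshot (1970/1980/1990/2000), or an inter-decadal change surface.
#' Missing cells are `NA`.
#'
#' @param name layer name (e.g. `"human_population"`).
#' @param values numeric vector of length `n_lon * n_lat`, row-major.
#' @param grid the `grid_spec` the layer lives on.
#' @param decade `NULL` for a static layer, a single decade year for a
#'   decadal snapshot, or a length-2 vector `c(from, to)` for a change layer.
#' @return An object of class `eid_layer`.
#' @export
layer <- function(name, values, grid, decade = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.numeric(values), length(values) == n_cells(grid))
  if (!is.null(decade)) {
    decade <- as.integer(decade)
    stopifnot(length(decade) %in% 1:2)
    if (length(decade) == 2L && decade[2] <= decade[1])
      stop("change-layer decades must be increasing")
  }
  structure(list(name = name, values = as.numeric(values), decade = decade,
                 n_lon = grid$n_lon, n_lat = grid$n_lat),
            class = "eid_layer")
}

#' @export
print.eid_layer <- function(x, ...) {
  tag <- if (is.null(x$decade)) "static"
         else paste(x$decade, collapse = "-")
  cat(sprintf("<layer> %s [%s] %dx%d, %d missing\n", x$name, tag,
              x$n_lon, x$n_lat, sum(is.na(x$values))))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (a$n_lon != b$n_lon || a$n_lat != b$n_lat)
    stop("layers are on different grids")
  invisible(TRUE)
}

#' Aggregate a fine-resolution field to the study grid
#'
#' Block-aggregates a field on a finer equal-angle grid to the study grid by
#' summing or averaging the constituent fine cells. Headcount-like quantities
#' (population, livestock, species-range overlaps) are summed; proportions
#' and index variables are averaged. The fine resolution must divide the
#' study resolution evenly.
#'
#' @param fine numeric matrix of fine cells, `fine[i, j]` = row i (south to
#'   north), column j (west to east); dimensions must be integer multiples of
#'   `grid$n_lat` and `grid$n_lon`.
#' @param grid target `grid_spec`.
#' @param method `"sum"` or `"mean"`. Missing fine cells count as 0 in a sum
#'   and are excluded from a mean (an all-missing block is `NA`).
#' @param name,decade passed to [layer()].
#' @return An `eid_layer` on `grid`.
#' @export
rescale_to_grid <- function(fine, grid, method = c("sum", "mean"),
                            name = "rescaled", decade = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(fine))
  fr <- nrow(fine) / grid$n_lat
  fc <- ncol(fine) / grid$n_lon
  if (fr != as.integer(fr) || fc != as.integer(fc))
    stop(sprintf(
      "fine grid %dx%d is not an integer refinement of the %dx%d study grid",
      nrow(fine), ncol(fine), grid$n_lat, grid$n_lon))
  fr <- as.integer(fr); fc <- as.integer(fc)
  # group fine rows/cols by coarse block and aggregate
  row_grp <- rep(seq_len(grid$n_lat), each = fr)
  col_grp <- rep(seq_len(grid$n_lon), each = fc)
  vals <- matrix(NA_real_, grid$n_lat, grid$n_lon)
  for (i in seq_len(grid$n_lat)) {
    block_rows <- fine[row_grp == i, , drop = FALSE]
    for (j in seq_len(grid$n_lon)) {
      b <- block_rows[, col_grp == j, drop = FALSE]
      vals[i, j] <- if (method == "sum") {
        sum(b, na.rm = TRUE)
      } else if (all(is.na(b))) NA_real_ else mean(b, na.rm = TRUE)
    }
  }
  layer(name, as.numeric(t(vals)), grid, decade = decade)
}

#' Difference two consecutive decadal snapshots
#'
#' Inter-decadal change surface: elementwise `later - earlier`. The inputs
#' must be the same variable at consecutive decades.
#'
#' @param later,earlier `eid_layer`s of the same name, with `later` one
#'   decade after `earlier`.
#' @return An `eid_layer` named `"<name>_change"` tagged with the decade
#'   interval `c(earlier, later)`.
#' @export
diff_decades <- function(later, earlier) {
  check_same_grid(later, earlier)
  if (later$name != earlier$name)
    stop(sprintf("cannot difference '%s' against '%s'",
                 later$name, earlier$name))
  if (is.null(later$decade) || is.null(earlier$decade) ||
      length(later$decade) != 1L || length(earlier$decade) != 1L)
    stop("diff_decades needs two single-decade snapshots")
  if (later$decade - earlier$decade != 10L)
    stop(sprintf("decades %d and %d are not consecutive",
                 earlier$decade, later$decade))
  out <- layer(paste0(later$name, "_change"),
               later$values - earlier$values,
               list(n_lon = later$n_lon, n_lat = later$n_lat),
               decade = c(earlier$decade, later$decade))
  out
}

#' Match an event year to its decadal covariate snapshot
#'
#' Years are matched to the nearest decade among 1970-2000; years ending in
#' 5 round up, and years after 2000 (through 2008) use the 2000 snapshot.
#' Events before 1970 have no covariates and are rejected.
#'
#' @param year calendar year(s), 1970-2008.
#' @return Decade year(s) in `{1970, 1980, 1990, 2000}`.
#' @export
match_decade <- function(year) {
  year <- as.integer(year)
  if (any(year < 1970L))
    stop("years before 1970 have no decadal covariates; filter events first")
  if (any(year > 2008L)) stop("years after 2008 are outside the study period")
  # nearest decade with ties (xxx5) rounding up; avoid round()'s half-to-even
  pmin(2000L, as.integer(floor((year + 5L) / 10L) * 10L))
}

# change-layer interval whose right endpoint is match_decade(year);
# 1970 has no preceding interval so it borrows 1970-1980
change_interval <- function(year) {
  md <- match_decade(year)
  right <- pmax(md, 1980L)
  cbind(from = right - 10L, to = right)
}

#' Sum livestock headcount layers
#'
#' Collapses several per-species headcount surfaces (buffalo, cattle, goats,
#' pigs, sheep) into one domestic-mammal layer. Missing cells count as 0.
#'
#' @param layers a non-empty list of `eid_layer`s on the same grid with the
#'   same temporal tag.
#' @param name name for the combined layer.
#' @return An `eid_layer`.
#' @export
sum_headcounts <- function(layers, name = "livestock_mammals") {
  if (length(layers) == 0L) stop("no layers to sum")
  base <- layers[[1]]
  for (l in layers[-1]) {
    check_same_grid(base, l)
    if (!identical(l$decade, base$decade))
      stop("headcount layers have mismatched temporal tags")
  }
  vals <- Reduce(`+`, lapply(layers, function(l) {
    v <- l$values; v[is.na(v)] <- 0; v
  }))
  layer(name, vals, list(n_lon = base$n_lon, n_lat = base$n_lat),
        decade = base$decade)
}

#' Standard-deviation scaling for map rendering
#'
#' Centres and scales values to z-scores and clips them to `[-k, k]`; map
#' palettes are anchored to k standard deviations either side of the mean.
#' Missing values propagate. A zero-variance input returns all zeros.
#'
#' @param x numeric vector (layer values).
#' @param k clip bound in standard deviations (default 2.5).
#' @return Scaled values in `[-k, k]`.
#' @export
sd_scale <- function(x, k = 2.5) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values to scale")
  s <- stats::sd(x[ok])
  if (s == 0) {
    out <- x
    out[ok] <- 0
    return(out)
  }
  z <- (x - mean(x[ok])) / s
  pmin(k, pmax(-k, z))
}

# ---- predictor sets ---------------------------------------------------------

#' Bundle covariate layers into a predictor set
#'
#' A predictor set holds every model covariate: static layers, decadal series
#' (all four snapshots 1970-2000), and the change series derived from them.
#' Querying by (name, year) resolves decadal names through [match_decade()]
#' and change names through the decade interval ending at the matched decade.
#'
#' @param layers a list of `eid_layer`s. Decadal snapshots of one variable
#'   share a name and differ in `decade`.
#' @param grid the common `grid_spec`.
#' @return An object of class `predictor_set`.
#' @export
predictor_set <- function(layers, grid) {
  ps <- list(static = list(), decadal = list(), change = list(), grid = grid)
  for (l in layers) {
    stopifnot(inherits(l, "eid_layer"))
    if (l$n_lon != grid$n_lon || l$n_lat != grid$n_lat)
      stop(sprintf("layer '%s' is not on the supplied grid", l$name))
    if (is.null(l$decade)) {
      ps$static[[l$name]] <- l
    } else if (length(l$decade) == 1L) {
      ps$decadal[[l$name]][[as.character(l$decade)]] <- l
    } else {
      ps$change[[l$name]][[paste(l$decade, collapse = "-")]] <- l
    }
  }
  decades <- lapply(ps$decadal, function(s) sort(as.integer(names(s))))
  if (length(decades) > 0) {
    ref <- decades[[1]]
    for (nm in names(decades))
      if (!identical(decades[[nm]], ref))
        stop(sprintf("decadal predictor '%s' has decades {%s}, expected {%s}",
                     nm, paste(decades[[nm]], collapse = ","),
                     paste(ref, collapse = ",")))
  }
  class(ps) <- "predictor_set"
  ps
}

#' @export
print.predictor_set <- function(x, ...) {
  cat(sprintf("<predictor_set> %d static, %d decadal, %d change series on %dx%d grid\n",
              length(x$static), length(x$decadal), length(x$change),
              x$grid$n_lon, x$grid$n_lat))
  invisible(x)
}

#' Derive inter-decadal change series for decadal predictors
#'
#' For each named decadal series, appends `<name>_change` layers for every
#' consecutive decade pair via [diff_decades()].
#'
#' @param pset a `predictor_set`.
#' @param names decadal predictor names to difference (default: all).
#' @return The augmented `predictor_set`.
#' @export
add_change_layers <- function(pset, names = base::names(pset$decadal)) {
  for (nm in names) {
    series <- pset$decadal[[nm]]
    if (is.null(series)) stop(sprintf("no decadal predictor '%s'", nm))
    decs <- sort(as.integer(base::names(series)))
    for (i in seq_along(decs)[-1]) {
      ch <- diff_decades(series[[as.character(decs[i])]],
                         series[[as.character(decs[i - 1])]])
      pset$change[[ch$name]][[paste(ch$decade, collapse = "-")]] <- ch
    }
  }
  pset
}

#' Names of all model predictors in a set
#'
#' @param pset a `predictor_set`.
#' @return Character vector: static names, then decadal names, then change
#'   names (fixed design-matrix column order).
#' @export
predictor_names <- function(pset) {
  c(names(pset$static), names(pset$decadal), names(pset$change))
}

#' Resolve one predictor at a calendar year
#'
#' @param pset a `predictor_set`.
#' @param name a predictor name (static, decadal, or change).
#' @param year calendar year used to pick the decadal snapshot / change
#'   interval; ignored for static layers.
#' @return The resolved `eid_layer`.
#' @export
get_layer <- function(pset, name, year = 2000L) {
  if (!is.null(pset$static[[name]])) return(pset$static[[name]])
  if (!is.null(pset$decadal[[name]])) {
    md <- as.character(match_decade(year))
    l <- pset$decadal[[name]][[md]]
    if (is.null(l)) stop(sprintf("predictor '%s' has no %s snapshot", name, md))
    return(l)
  }
  if (!is.null(pset$change[[name]])) {
    iv <- change_interval(year)
    key <- paste(iv[1, ], collapse = "-")
    l <- pset$change[[name]][[key]]
    if (is.null(l)) stop(sprintf("predictor '%s' has no %s interval", name, key))
    return(l)
  }
  stop(sprintf("unknown predictor '%s'", name))
}

#' Cells with complete predictor coverage
#'
#' Land cells where every predictor (every decade and change interval) is
#' non-missing; only these are eligible for background sampling.
#'
#' @param pset a `predictor_set`.
#' @return Logical vector over grid cells.
#' @export
complete_cells <- function(pset) {
  ok <- pset$grid$land_mask
  all_layers <- c(pset$static,
                  unlist(pset$decadal, recursive = FALSE),
                  unlist(pset$change, recursive = FALSE))
  for (l in all_layers) ok <- ok & !is.na(l$values)
  ok
}

# ---- layer IO ---------------------------------------------------------------

#' Write layers to long-format CSV
#'
#' One row per cell per layer: `lon, lat, name, decade, value`. The `decade`
#' column is empty for static layers and `"from-to"` for change layers.
#' Round-trips losslessly with [read_layers_csv()] (values printed at full
#' double precision).
#'
#' @param layers a list of `eid_layer`s (or a single layer).
#' @param grid their `grid_spec`.
#' @param path output CSV path.
#' @export
write_layers_csv <- function(layers, grid, path) {
  if (inherits(layers, "eid_layer")) layers <- list(layers)
  rows <- lapply(layers, function(l) {
    data.frame(lon = grid$lon, lat = grid$lat, name = l$name,
               decade = if (is.null(l$decade)) "" else
                 paste(l$decade, collapse = "-"),
               value = l$values)
  })
  df <- do.call(rbind, rows)
  # full precision so the CSV dialect round-trips exactly
  df$value <- formatC(df$value, digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read layers from long-format CSV
#'
#' @param path CSV written by [write_layers_csv()].
#' @param grid the `grid_spec` to attach them to.
#' @return A named-by-position list of `eid_layer`s.
#' @export
read_layers_csv <- function(path, grid) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(decade = "character"))
  idx <- cell_index(grid, df$lon, df$lat)
  key <- paste(df$name, df$decade, sep = "@")
  out <- list()
  for (k in unique(key)) {
    sub <- df[key == k, ]
    vals <- rep(NA_real_, n_cells(grid))
    # literal "NA" strings are intended missing values
    vals[cell_index(grid, sub$lon, sub$lat)] <-
      suppressWarnings(as.numeric(sub$value))
    dec <- sub$decade[1]
    decade <- if (dec == "") NULL else as.integer(strsplit(dec, "-")[[1]])
    out[[length(out) + 1L]] <- layer(sub$name[1], vals, grid, decade = decade)
  }
  out
}
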