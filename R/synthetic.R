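#' Synthetic-world configuration
#'
#' Parameters of the simulated study system: a coarse global grid of
#' spatially autocorrelated covariate fields shaped like the real predictor
#' stack (population, land use with decadal drift, land cover, host
#' richness, climate), a known logistic true-risk surface driven by a small
#' predictor subset, an urban-skewed reporting-effort surface, and emergence
#' events detected proportional to risk times effort.
#'
#' Defaults define the simulation study conditions: a 40 x 20 grid
#' (~60% land), 147 events (the size of the filtered wildlife-zoonosis
#' record), three active drivers among the 20 predictors — tropical forest
#' (evergreen broadleaf trees), mammal species richness and pasture change,
#' mirroring the field's leading hypotheses — and detection fully coupled to
#' reporting effort (`bias_strength = 1`).
#'
#' @param n_lon,n_lat grid dimensions.
#' @param n_events number of emergence events (>= 10).
#' @param drivers named vector of logistic coefficients on standardised
#'   drivers.
#' @param intercept logistic intercept.
#' @param bias_strength exponent coupling detection probability to
#'   reporting effort (0 = unbiased detection).
#' @param footprint_precision fraction of events geocoded to a single cell.
#' @param max_block largest footprint block edge (cells) for imprecise
#'   events.
#' @param land_fraction fraction of cells that are land.
#' @param smooth_sigma Gaussian smoothing radius (cells) of the random
#'   fields.
#' @param urban_pop_rho latent correlation between urban land and
#'   population.
#' @param effort_gamma,effort_delta effort log-intensity loadings on
#'   standardised urban land and log population.
#' @param effort_noise_sd smooth log-normal noise in the effort intensity.
#' @param n_articles synthetic articles in the toponym match table.
#' @param decades decadal snapshot years.
#' @param seed RNG seed; the whole world is reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_lon = 40L, n_lat = 20L, n_events = 147L,
                         drivers = c(evergreen_broadleaf = 1.2,
                                     mammal_richness = 1.0,
                                     pasture_change = 0.8),
                         intercept = -2, bias_strength = 1,
                         footprint_precision = 0.5, max_block = 4L,
                         land_fraction = 0.6, smooth_sigma = 1.5,
                         urban_pop_rho = 0.7, effort_gamma = 1.2,
                         effort_delta = 0.6, effort_noise_sd = 0.4,
                         n_articles = 500L,
                         decades = c(1970L, 1980L, 1990L, 2000L),
                         seed = 1L) {
  stopifnot(n_events >= 10L, bias_strength >= 0, all(is.finite(drivers)),
            footprint_precision >= 0, footprint_precision <= 1,
            max_block >= 1L, land_fraction > 0, land_fraction <= 1)
  structure(as.list(environment()), class = "synth_config")
}

# smooth a white-noise matrix with a separable Gaussian kernel,
# renormalising at the edges, and return a standardised field
smooth_field <- function(n_row, n_col, sigma) {
  z <- matrix(stats::rnorm(n_row * n_col), n_row, n_col)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  conv1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      wk <- w[j - i + r + 1L]
      out[i] <- sum(v[j] * wk) / sum(wk)
    }
    out
  }
  z <- apply(z, 2, conv1)
  z <- t(apply(z, 1, conv1))
  v <- as.numeric(t(z))  # row-major cell order
  (v - mean(v)) / stats::sd(v)
}

std_land <- function(values, land) {
  v <- values[land]
  (values - mean(v)) / stats::sd(v)
}

#' Generate the synthetic predictor stack
#'
#' Builds 19 named analogues of the real covariates (the 20th, reporting
#' effort, comes from [gen_effort()]): 12 static layers (land-cover
#' percentages, mammal richness, livestock and poultry headcounts, a climate
#' stratification index, managed vegetation), 4 decadal series (population,
#' cropland, pasture, urban land) with smooth drift so change layers are
#' non-trivial, and the 3 derived change series. Urban land shares a latent
#' field with population (correlation `urban_pop_rho`); percentage layers
#' are clipped to [0, 100].
#'
#' @param config a `synth_config`.
#' @param grid the world's `grid_spec`.
#' @return A `predictor_set` (change layers included).
#' @export
gen_predictors <- function(config, grid) {
  nr <- grid$n_lat; nc <- grid$n_lon
  sf <- function() smooth_field(nr, nc, config$smooth_sigma)
  pct <- function(z) pmin(100, pmax(0, 50 + 25 * z))
  prop <- function(z) pmin(1, pmax(0, 0.4 + 0.2 * z))

  layers <- list()
  static_specs <- list(
    managed_vegetation = pct, gens = function(z) 50 + 20 * z,
    mammal_richness = function(z) round(pmax(0, 80 + 40 * z)),
    livestock_mammals = function(z) exp(4 + z),
    poultry = function(z) exp(4 + z),
    needleleaf_trees = pct, evergreen_broadleaf = pct,
    deciduous_broadleaf = pct, mixed_trees = pct, shrubs = pct,
    herbaceous = pct, flooded_vegetation = pct)
  for (nm in names(static_specs))
    layers[[length(layers) + 1L]] <-
      layer(nm, static_specs[[nm]](sf()), grid)

  # decadal latent process: base + linear drift + per-decade innovation,
  # standardised per decade, then the unit transform
  latents <- function() {
    base <- sf(); drift <- sf()
    lapply(seq_along(config$decades), function(i) {
      z <- base + 0.15 * (i - 1L) * drift + 0.05 * sf()
      (z - mean(z)) / stats::sd(z)
    })
  }
  z_pop <- latents()
  # urban shares the population latent decade by decade, so the target
  # correlation is not diluted by independent drift
  rho <- config$urban_pop_rho
  z_urb_own <- latents()
  z_urban <- lapply(seq_along(config$decades), function(i)
    rho * z_pop[[i]] + sqrt(1 - rho^2) * z_urb_own[[i]])
  decadal_specs <- list(
    human_population = list(z = z_pop, f = function(z) exp(3 + z)),
    cropland = list(z = latents(), f = prop),
    pasture = list(z = latents(), f = prop),
    urban = list(z = z_urban, f = pct))
  for (nm in names(decadal_specs)) {
    spec <- decadal_specs[[nm]]
    for (i in seq_along(config$decades))
      layers[[length(layers) + 1L]] <-
        layer(nm, spec$f(spec$z[[i]]), grid, decade = config$decades[i])
  }
  pset <- predictor_set(layers, grid)
  add_change_layers(pset,
                    names = c("human_population", "cropland", "pasture"))
}

#' Generate the known true-risk surface
#'
#' `logistic(intercept + sum(beta_j * standardised driver_j))` evaluated at
#' the 2000 snapshot (standardisation over land cells). Deterministic given
#' the predictors; the returned metadata suffices to recompute it exactly.
#'
#' @param predictors `predictor_set` from [gen_predictors()].
#' @param config a `synth_config`.
#' @return List with `risk` (`eid_layer`, values in (0,1) on land, NA on
#'   ocean) and `metadata` (coefficients and standardisation constants).
#' @export
gen_true_risk <- function(predictors, config) {
  grid <- predictors$grid
  land <- grid$land_mask
  eta <- rep(config$intercept, n_cells(grid))
  meta <- list(intercept = config$intercept, drivers = list())
  for (nm in names(config$drivers)) {
    l <- get_layer(predictors, nm, 2000L)  # errors on unknown driver names
    mu <- mean(l$values[land]); s <- stats::sd(l$values[land])
    eta <- eta + config$drivers[[nm]] * (l$values - mu) / s
    meta$drivers[[nm]] <- list(beta = config$drivers[[nm]], mean = mu,
                               sd = s)
  }
  v <- stats::plogis(eta)
  v[!land] <- NA_real_
  list(risk = layer("true_risk", v, grid), metadata = meta)
}

#' Generate the biased reporting-effort surface
#'
#' Per-cell article intensity is log-linear in standardised urban land and
#' log population plus smooth noise — emulating the urban skew of the
#' literature. A synthetic per-article toponym match table is emitted and
#' pushed through the real effort pipeline ([aggregate_matches()] then
#' [smooth_effort()]), so the module under test builds the layer.
#'
#' @param predictors `predictor_set`.
#' @param config a `synth_config`.
#' @return List with `matches` (data frame), `effort` (an `effort_layer`),
#'   and `intensity` (the generative rate, land cells).
#' @export
gen_effort <- function(predictors, config) {
  grid <- predictors$grid
  land_idx <- which(grid$land_mask)
  urban <- std_land(get_layer(predictors, "urban", 2000L)$values,
                    grid$land_mask)
  logpop <- std_land(log(get_layer(predictors, "human_population",
                                   2000L)$values),
                     grid$land_mask)
  noise <- smooth_field(grid$n_lat, grid$n_lon, config$smooth_sigma)
  log_int <- config$effort_gamma * urban + config$effort_delta * logpop +
    config$effort_noise_sd * noise
  intensity <- exp(log_int[land_idx])

  n_match <- 1L + stats::rpois(config$n_articles, 2)
  rows <- vector("list", config$n_articles)
  for (a in seq_len(config$n_articles)) {
    cells <- land_idx[sample.int(length(land_idx), n_match[a],
                                 replace = TRUE, prob = intensity)]
    rows[[a]] <- data.frame(
      article_id = sprintf("a%04d", a),
      lon = grid$lon[cells] + stats::runif(n_match[a], -0.4, 0.4) * grid$dlon,
      lat = grid$lat[cells] + stats::runif(n_match[a], -0.4, 0.4) * grid$dlat,
      raw_weight = stats::rexp(n_match[a]))
  }
  matches <- do.call(rbind, rows)
  raw <- aggregate_matches(matches, grid)
  eff <- smooth_effort(raw, predictors,
                       covariate_names = c("human_population", "urban",
                                           "gens"),
                       seed = config$seed)
  list(matches = matches, effort = eff, intensity = intensity)
}

#' Sample emergence events from the true risk and detection bias
#'
#' Event cells are drawn (with replacement) proportional to
#' `true_risk * effort^bias_strength` over land; years are uniform on
#' 1970-2008. With probability `footprint_precision` an event keeps its
#' single true cell (a precise point with its 5 km buffer); otherwise its
#' footprint is the land portion of an up-to-`max_block`-square block around
#' the true cell, emulating municipal- to country-scale geocoding.
#'
#' @param true_risk true-risk `eid_layer`.
#' @param effort smoothed effort `eid_layer`.
#' @param config a `synth_config`.
#' @param grid the `grid_spec`.
#' @return List of `eid_event`s (attribute `"true_cell"` records the
#'   generative cell of each event).
#' @export
gen_events <- function(true_risk, effort, config, grid) {
  land_idx <- which(grid$land_mask)
  w <- true_risk$values[land_idx] *
    (effort$values[land_idx])^config$bias_strength
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("degenerate event sampling weights (all zero)")
  cells <- land_idx[sample.int(length(land_idx), config$n_events,
                               replace = TRUE, prob = w)]
  years <- sample(1970:2008, config$n_events, replace = TRUE)
  precise <- stats::runif(config$n_events) < config$footprint_precision
  events <- vector("list", config$n_events)
  for (i in seq_len(config$n_events)) {
    if (precise[i]) {
      fp <- cells[i]
    } else {
      k <- sample(2:config$max_block, 1L)
      r0 <- (cells[i] - 1L) %/% grid$n_lon + 1L
      c0 <- (cells[i] - 1L) %% grid$n_lon + 1L
      rows <- max(1L, r0 - k %/% 2L):min(grid$n_lat, r0 + (k - 1L) %/% 2L)
      cols <- max(1L, c0 - k %/% 2L):min(grid$n_lon, c0 + (k - 1L) %/% 2L)
      block <- as.integer(outer(cols, (rows - 1L) * grid$n_lon, `+`))
      fp <- block[grid$land_mask[block]]
    }
    events[[i]] <- eid_event(sprintf("ev%03d", i), years[i], fp,
                             precise = precise[i])
    attr(events[[i]], "true_cell") <- cells[i]
  }
  events
}

#' Generate a complete synthetic world
#'
#' Land mask, predictors, true risk, reporting effort (via the real effort
#' pipeline) and events, all reproducible from `config$seed`. Stages draw
#' from stage-offset seeded streams so each component is individually
#' reproducible.
#'
#' @param config a `synth_config`.
#' @return A `synth_world`: `grid`, `predictors` (including the smoothed
#'   `reporting_effort` layer as the 20th predictor), `true_risk`, `effort`
#'   (`effort_layer`), `matches`, `events`, `metadata`.
#' @export
gen_world <- function(config = synth_config()) {
  set.seed(config$seed)
  zl <- smooth_field(config$n_lat, config$n_lon, config$smooth_sigma * 1.5)
  mask <- zl >= stats::quantile(zl, 1 - config$land_fraction)
  grid <- grid_spec(config$n_lon, config$n_lat, land_mask = mask)

  set.seed(config$seed + 1L)
  predictors <- gen_predictors(config, grid)
  tr <- gen_true_risk(predictors, config)

  set.seed(config$seed + 2L)
  eff <- gen_effort(predictors, config)

  set.seed(config$seed + 3L)
  events <- gen_events(tr$risk, eff$effort$smoothed, config, grid)

  # reporting effort joins the predictor stack as its 20th member
  predictors <- predictor_set(
    c(list(eff$effort$smoothed),
      predictors$static,
      unlist(predictors$decadal, recursive = FALSE, use.names = FALSE),
      unlist(predictors$change, recursive = FALSE, use.names = FALSE)),
    grid)

  structure(list(grid = grid, predictors = predictors, true_risk = tr$risk,
                 effort = eff$effort, matches = eff$matches,
                 events = events,
                 metadata = c(tr$metadata, list(config = config))),
            class = "synth_world")
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf(
    "<synth_world> %dx%d grid (%d land), %d predictors, %d events, drivers: %s\n",
    x$grid$n_lon, x$grid$n_lat, sum(x$grid$land_mask),
    length(predictor_names(x$predictors)), length(x$events),
    paste(names(x$metadata$config$drivers), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic world to plain-text files
#'
#' Layers (predictors, true risk, raw and smoothed effort) as long CSV, the
#' toponym match table as CSV, events as GeoJSON, and the generative
#' metadata as JSON, under `dir`.
#'
#' @param world a `synth_world`.
#' @param dir output directory (created if needed).
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- world$predictors
  all_layers <- c(ps$static,
                  unlist(ps$decadal, recursive = FALSE, use.names = FALSE),
                  unlist(ps$change, recursive = FALSE, use.names = FALSE))
  write_layers_csv(all_layers, world$grid, file.path(dir, "predictors.csv"))
  write_layers_csv(list(world$true_risk, world$effort$raw,
                        world$effort$smoothed),
                   world$grid, file.path(dir, "surfaces.csv"))
  utils::write.csv(world$matches, file.path(dir, "matches.csv"),
                   row.names = FALSE)
  write_events_geojson(world$events, world$grid,
                       file.path(dir, "events.geojson"))
  jsonlite::write_json(world$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
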