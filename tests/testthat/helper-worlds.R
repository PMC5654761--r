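# Shared fixtures: worlds are generated once per test run and memoised.

.world_cache <- new.env(parent = emptyenv())

# small world for cheap unit tests (fewer events, small grid)
small_world <- function(seed = 101L) {
  key <- paste0("small", seed)
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- gen_world(synth_config(
      n_lon = 24L, n_lat = 12L, n_events = 40L, n_articles = 150L,
      seed = seed))
  .world_cache[[key]]
}

# default-condition world (40x20, 147 events) for heavier checks
default_world <- function(seed = 1L) {
  key <- paste0("default", seed)
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- gen_world(synth_config(seed = seed))
  .world_cache[[key]]
}

# quick boosting config for API-level tests where fit quality is irrelevant
fast_boost <- function(...) {
  boost_config(learning_rate = 0.05, step_size = 20L,
               internal_cv_folds = 3L, max_trees = 400L, patience = 2L,
               max_bin = 32L, ...)
}

# tiny deterministic grid helpers
flat_grid <- function(n_lon = 8L, n_lat = 4L, land = NULL) {
  grid_spec(n_lon, n_lat, land_mask = land)
}

const_layer <- function(grid, value, name = "const", decade = NULL) {
  layer(name, rep(value, grid$n_lon * grid$n_lat), grid, decade = decade)
}
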