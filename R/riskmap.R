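#' Fit the bootstrap BRT ensemble and aggregate it
#'
#' Fits `config$n_replicates` replicate models, each on one bootstrap draw
#' of events with fresh presence/absence cells (propagating sampling and
#' geocoding uncertainty), predicts every eligible land cell at the
#' reference decade, and aggregates: the per-cell mean prediction (the
#' response map), per-predictor relative-influence distributions
#' (min / quartiles / max with 1.5-IQR whiskers), and partial-dependence
#' bands (median and empirical 90% CI) on a probe grid common to all
#' replicates (10th-90th percentile of the pooled sampled values).
#' Replicates whose gradient descent fails (null models) are excluded from
#' every aggregate and counted.
#'
#' @param events list of `eid_event`s.
#' @param predictors `predictor_set`.
#' @param effort effort `eid_layer`.
#' @param config `resampling_config` (replicates and weighting mode).
#' @param boost `boost_config`.
#' @param seed RNG seed.
#' @param pd_predictors predictor names for partial-dependence bands
#'   (`NULL` to skip, `TRUE` for all predictors).
#' @param n_probe probe-grid size for the bands.
#' @param reference_year decade at which map predictions are made (default
#'   2000, with the 1990-2000 change layers).
#' @return An `ensemble_result`: `mean_response` (`eid_layer`),
#'   `influence` (per-replicate matrix), `influence_summary` (box-plot
#'   stats), `pd_bands`, `n_trees`, `deviance_explained`, `n_null`.
#' @export
run_ensemble <- function(events, predictors, effort, config,
                         boost = boost_config(), seed = 1L,
                         pd_predictors = NULL, n_probe = 25L,
                         reference_year = 2000L) {
  stopifnot(config$n_replicates >= 2L)
  set.seed(seed)
  grid <- predictors$grid
  nms <- predictor_names(predictors)
  eligible <- which(complete_cells(predictors))

  # draw all replicate designs first so partial-dependence probe grids can
  # pool the sampled values across replicates
  designs <- lapply(seq_len(config$n_replicates), function(r)
    assemble_design(bootstrap_replicate(events, effort, predictors, config),
                    predictors))

  if (isTRUE(pd_predictors)) pd_predictors <- nms
  probe_grids <- NULL
  if (!is.null(pd_predictors)) {
    probe_grids <- lapply(pd_predictors, function(nm) {
      pooled <- unlist(lapply(designs, function(d) d$x[, nm]))
      q <- stats::quantile(pooled, c(0.1, 0.9), names = FALSE)
      seq(q[1], q[2], length.out = n_probe)
    })
    names(probe_grids) <- pd_predictors
  }

  # map-prediction design: every eligible cell at the reference decade
  x_map <- matrix(NA_real_, length(eligible), length(nms),
                  dimnames = list(NULL, nms))
  for (nm in nms)
    x_map[, nm] <- get_layer(predictors, nm, reference_year)$values[eligible]

  n_rep <- config$n_replicates
  pred_sum <- rep(0, length(eligible))
  influence <- matrix(NA_real_, n_rep, length(nms),
                      dimnames = list(NULL, nms))
  pd_curves <- lapply(pd_predictors, function(nm)
    matrix(NA_real_, n_rep, n_probe))
  names(pd_curves) <- pd_predictors
  n_trees <- integer(n_rep)
  dev_expl <- rep(NA_real_, n_rep)
  null_flags <- logical(n_rep)

  for (r in seq_len(n_rep)) {
    # release dead engine handles (native memory invisible to the R gc)
    if (r %% 10L == 0L) gc(verbose = FALSE)
    fit <- suppressWarnings(fit_step(designs[[r]], boost))
    null_flags[r] <- fit$null_model
    n_trees[r] <- fit$n_trees_selected
    if (fit$null_model) next
    pred_sum <- pred_sum + predict(fit, x_map)
    influence[r, ] <- relative_influence(fit)
    dev_expl[r] <- deviance_explained(fit)
    for (nm in pd_predictors)
      pd_curves[[nm]][r, ] <- partial_dependence(
        fit, nm, designs[[r]]$x, probe_values = probe_grids[[nm]])$yhat
  }

  n_ok <- sum(!null_flags)
  if (n_ok == 0L) stop("every replicate returned a null model")
  vals <- rep(NA_real_, n_cells(grid))
  vals[eligible] <- pred_sum / n_ok
  influence <- influence[!null_flags, , drop = FALSE]

  pd_bands <- lapply(pd_predictors, function(nm) {
    m <- pd_curves[[nm]][!null_flags, , drop = FALSE]
    q <- apply(m, 2, stats::quantile, probs = c(0.05, 0.5, 0.95),
               names = FALSE)
    data.frame(predictor = nm, value = probe_grids[[nm]],
               q05 = q[1, ], median = q[2, ], q95 = q[3, ])
  })
  names(pd_bands) <- pd_predictors

  structure(list(
    mean_response = layer("response", vals, grid),
    influence = influence,
    influence_summary = influence_boxstats(influence),
    pd_bands = pd_bands,
    n_trees = n_trees[!null_flags],
    deviance_explained = dev_expl[!null_flags],
    n_null = sum(null_flags),
    mode = config$mode,
    reference_year = reference_year
  ), class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  top <- names(sort(x$influence_summary$median, decreasing = TRUE))[1:3]
  cat(sprintf(
    "<ensemble_result> %d replicates (%d null), mean %.0f trees, median deviance explained %.1f%%\n",
    nrow(x$influence) + x$n_null, x$n_null, mean(x$n_trees),
    stats::median(x$deviance_explained)))
  cat("  top influence:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

# box-plot statistics per predictor (whiskers: extreme datum within 1.5 IQR)
influence_boxstats <- function(influence) {
  q <- apply(influence, 2, stats::quantile,
             probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  iqr <- q[4, ] - q[2, ]
  lo <- hi <- numeric(ncol(influence))
  for (j in seq_len(ncol(influence))) {
    x <- influence[, j]
    lo[j] <- min(x[x >= q[2, j] - 1.5 * iqr[j]])
    hi[j] <- max(x[x <= q[4, j] + 1.5 * iqr[j]])
  }
  list(min = q[1, ], q25 = q[2, ], median = q[3, ], q75 = q[4, ],
       max = q[5, ], whisker_low = stats::setNames(lo, colnames(influence)),
       whisker_high = stats::setNames(hi, colnames(influence)))
}

#' Observed EID risk index
#'
#' The weighted model's response is relative to reporting effort;
#' multiplying it back by effort maps the index of risk of *observing* an
#' event under current surveillance.
#'
#' @param response response `eid_layer` (ensemble mean).
#' @param effort effort `eid_layer`.
#' @return Product `eid_layer` named `"observed_risk_index"`.
#' @export
observed_index <- function(response, effort) {
  check_same_grid(response, effort)
  layer("observed_risk_index", response$values * effort$values,
        list(n_lon = response$n_lon, n_lat = response$n_lat))
}

#' Reporting bias surface
#'
#' Reporting bias is taken proportional to the ratio of reporting effort to
#' human population: the departure of surveillance from the assumed optimum
#' (effort proportional to population). Cells with nonpositive population
#' are masked.
#'
#' @param effort,population `eid_layer`s on the same grid.
#' @return Ratio `eid_layer` named `"reporting_bias"`.
#' @export
reporting_bias <- function(effort, population) {
  check_same_grid(effort, population)
  v <- effort$values / population$values
  v[!is.na(population$values) & population$values <= 0] <- NA_real_
  layer("reporting_bias", v,
        list(n_lon = effort$n_lon, n_lat = effort$n_lat))
}

#' Bias-corrected (true) EID risk index
#'
#' Factors measured reporting effort out of the observed index and factors
#' the assumed-optimal (population-proportional) effort in:
#' `observed * population / effort`. Algebraically this equals
#' `response * population`; cells where effort is at or below the floor are
#' masked rather than extrapolated.
#'
#' @param observed observed-index `eid_layer`.
#' @param population,effort `eid_layer`s on the same grid.
#' @param floor positive effort floor below which cells are masked
#'   (default: the smoothing floor, 0 keeps everything positive).
#' @return `eid_layer` named `"corrected_risk_index"`.
#' @export
corrected_index <- function(observed, population, effort, floor = 0) {
  check_same_grid(observed, effort)
  check_same_grid(observed, population)
  v <- observed$values * population$values / effort$values
  v[!is.na(effort$values) & effort$values <= floor] <- NA_real_
  layer("corrected_risk_index", v,
        list(n_lon = observed$n_lon, n_lat = observed$n_lat))
}

#' Render a risk layer as a standard-deviation-scaled heat map
#'
#' Applies [sd_scale()] (palette anchored k standard deviations either side
#' of the mean) and draws a lon/lat tile map; optionally writes the PNG and
#' the scaled layer as CSV.
#'
#' @param map an `eid_layer`.
#' @param grid its `grid_spec`.
#' @param png_path optional PNG output path.
#' @param csv_path optional CSV output path for the scaled layer.
#' @param k clip bound in standard deviations.
#' @return Invisibly, a list with the scaled `eid_layer` and the ggplot.
#' @export
render_map <- function(map, grid, png_path = NULL, csv_path = NULL, k = 2.5) {
  scaled <- layer(paste0(map$name, "_scaled"), sd_scale(map$values, k = k),
                  grid)
  df <- data.frame(lon = grid$lon, lat = grid$lat, value = scaled$values)
  p <- ggplot2::ggplot(df[!is.na(df$value), ],
                       ggplot2::aes(x = lon, y = lat, fill = value)) +
    ggplot2::geom_tile(width = grid$dlon, height = grid$dlat) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7",
                                  high = "#b2182b", limits = c(-k, k),
                                  name = "s.d.") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = map$name, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(png_path))
    ggplot2::ggsave(png_path, p, width = 8, height = 4.5, dpi = 150)
  if (!is.null(csv_path)) write_layers_csv(scaled, grid, csv_path)
  invisible(list(scaled = scaled, plot = p))
}
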