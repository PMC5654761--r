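#' Aggregate per-article toponym matches to the study grid
#'
#' Each biomedical article contributes total mass 1: its toponym-match
#' weights are rescaled to sum to one, then scattered into the grid cells
#' containing the matched place coordinates and summed over articles. The
#' result is invariant to rescaling any single article's raw weights, and
#' its global total equals the number of contributing articles.
#'
#' @param matches data frame with columns `article_id`, `lon`, `lat`,
#'   `raw_weight` (nonnegative). Articles whose weights are all zero are
#'   dropped with a warning.
#' @param grid a `grid_spec`.
#' @return An `eid_layer` named `"reporting_effort_raw"` (zeros where no
#'   matches fell).
#' @export
aggregate_matches <- function(matches, grid) {
  stopifnot(all(c("article_id", "lon", "lat", "raw_weight") %in%
                  names(matches)))
  if (any(matches$raw_weight < 0)) stop("raw weights must be nonnegative")
  vals <- rep(0, n_cells(grid))
  if (nrow(matches) > 0) {
    tot <- tapply(matches$raw_weight, matches$article_id, sum)
    dead <- names(tot)[tot == 0]
    if (length(dead) > 0) {
      warning(sprintf("dropping %d article(s) with all-zero weights",
                      length(dead)))
      matches <- matches[!(matches$article_id %in% dead), , drop = FALSE]
    }
    if (nrow(matches) > 0) {
      w <- matches$raw_weight /
        as.numeric(tot[as.character(matches$article_id)])
      idx <- cell_index(grid, matches$lon, matches$lat)
      agg <- tapply(w, idx, sum)
      vals[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  layer("reporting_effort_raw", vals, grid)
}

# mean Poisson deviance: 2 * mean(y log(y/mu) - (y - mu)), y log y -> 0 at 0
poisson_deviance <- function(y, mu) {
  mu <- pmax(mu, 1e-12)
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * mean(term - (y - mu))
}

#' Smooth and impute the raw effort surface with a Poisson boosted-tree model
#'
#' The article-normalised effort counts are noisy and full of zeros where the
#' literature simply mentions no toponym; a Poisson boosted regression tree
#' on socioeconomic covariates (population, urban land, and whatever else is
#' supplied) smooths the surface and imputes those cells. Training and
#' prediction are restricted to land cells; predictions are strictly
#' positive, with a machine-epsilon-scaled floor so downstream weighted
#' sampling never divides by zero.
#'
#' @param raw raw effort layer from [aggregate_matches()].
#' @param covariates a `predictor_set` (or subset) supplying the smoothing
#'   covariates, complete on land cells.
#' @param covariate_names which predictors to use (default: all in
#'   `covariates`, resolved at `year`).
#' @param year decade used to resolve decadal covariates (default 2000).
#' @param max_depth,learning_rate,max_trees,cv_folds Poisson booster
#'   hyperparameters; the tree count is chosen by k-fold CV Poisson deviance.
#' @param seed RNG seed for the CV fold assignment.
#' @return An object of class `effort_layer`: fields `raw`, `smoothed`
#'   (both `eid_layer`s), `covariates_used`, `floor`, `n_trees`.
#' @export
smooth_effort <- function(raw, covariates,
                          covariate_names = predictor_names(covariates),
                          year = 2000L, max_depth = 3L, learning_rate = 0.01,
                          max_trees = 800L, cv_folds = 5L, seed = 1L) {
  grid <- covariates$grid
  check_same_grid(raw, list(n_lon = grid$n_lon, n_lat = grid$n_lat))
  land <- which(grid$land_mask)
  X <- vapply(covariate_names,
              function(nm) get_layer(covariates, nm, year)$values[land],
              numeric(length(land)))
  if (any(is.na(X))) stop("smoothing covariates must be complete on land")
  y <- raw$values[land]
  stopifnot(all(!is.na(y)), all(y >= 0))

  if (all(apply(X, 2, function(col) stats::var(col) == 0)) || all(y == 0)) {
    warning("degenerate covariates or all-zero effort; using global mean rate")
    rate <- rep(max(mean(y), 1e-9), length(land))
    n_trees <- 0L
  } else {
    set.seed(seed)
    folds <- sample(rep_len(seq_len(cv_folds), length(land)))
    grid_pts <- seq(25L, max_trees, by = 25L)
    cv_pred <- matrix(NA_real_, length(land), length(grid_pts))
    params <- list(objective = "count:poisson", max_depth = max_depth,
                   eta = learning_rate, nthread = 1)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
      m <- xgboost::xgb.train(params, dtr, nrounds = max_trees, verbose = 0)
      for (j in seq_along(grid_pts))
        cv_pred[!tr, j] <- predict(m, X[!tr, , drop = FALSE],
                                   iterationrange = c(1, grid_pts[j]))
    }
    dev <- apply(cv_pred, 2, function(mu) poisson_deviance(y, mu))
    n_trees <- grid_pts[which.min(dev)]
    dfull <- xgboost::xgb.DMatrix(X, label = y)
    m <- xgboost::xgb.train(params, dfull, nrounds = n_trees, verbose = 0)
    rate <- predict(m, X)
  }
  floor_val <- .Machine$double.eps * max(rate)
  rate <- pmax(rate, floor_val)
  smoothed_vals <- rep(NA_real_, n_cells(grid))
  smoothed_vals[land] <- rate
  structure(list(raw = raw,
                 smoothed = layer("reporting_effort", smoothed_vals, grid),
                 covariates_used = covariate_names,
                 floor = floor_val, n_trees = n_trees),
            class = "effort_layer")
}

#' @export
print.effort_layer <- function(x, ...) {
  cat(sprintf("<effort_layer> %d trees, covariates: %s\n", x$n_trees,
              paste(x$covariates_used, collapse = ", ")))
  invisible(x)
}

#' Read a toponym match table
#'
#' @param path CSV with columns `article_id, lon, lat, raw_weight`.
#' @return A data frame.
#' @export
read_match_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
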