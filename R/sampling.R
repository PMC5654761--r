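#' Resampling configuration
#'
#' Controls the bootstrap/CV draw machinery. In `weighted` mode background
#' (absence) cells are drawn proportional to reporting effort — the
#' target-group bias correction — so the fitted response is relative to
#' effort. In `unweighted` mode absences are drawn proportional to land area
#' per cell, removing the latitude-dependent cell-size bias of an equal-angle
#' grid but ignoring effort.
#'
#' @param n_replicates bootstrap replicates (study default 1000).
#' @param mode `"weighted"` or `"unweighted"`.
#' @param pair_folds keep each presence/absence pair in the same CV fold
#'   (default TRUE).
#' @return A `resampling_config` list.
#' @export
resampling_config <- function(n_replicates = 1000L,
                              mode = c("weighted", "unweighted"),
                              pair_folds = TRUE) {
  mode <- match.arg(mode)
  stopifnot(n_replicates >= 1L)
  structure(list(n_replicates = as.integer(n_replicates), mode = mode,
                 pair_folds = isTRUE(pair_folds)),
            class = "resampling_config")
}

# one weighted categorical draw; NA weights treated as 0
draw_weighted_cell <- function(cells, weights) {
  weights[is.na(weights)] <- 0
  if (length(cells) == 1L) return(cells)
  tot <- sum(weights)
  if (tot <= 0) return(cells[sample.int(length(cells), 1L)])
  cells[sample.int(length(cells), 1L, prob = weights)]
}

#' Draw a presence cell from an event footprint
#'
#' One cell from the event's candidate cells, with probability proportional
#' to reporting effort over the footprint (the spatial-uncertainty prior:
#' absent other knowledge, the event was more likely detected where effort
#' is higher). If the footprint carries zero total effort the draw falls
#' back to uniform.
#'
#' @param event an `eid_event`.
#' @param effort effort `eid_layer` (or any weight layer for the fallback
#'   modes).
#' @return A single cell index.
#' @export
draw_presence <- function(event, effort) {
  draw_weighted_cell(event$footprint, effort$values[event$footprint])
}

#' Draw a background (absence) cell
#'
#' One cell from all eligible land cells (complete predictors), with
#' probability proportional to the supplied weight layer: reporting effort
#' in weighted mode, land area in unweighted mode. Background draws are
#' pseudo-absences — they may coincide with presence cells of other pairs.
#'
#' @param eligible integer indices of eligible cells.
#' @param weight_layer numeric weights per grid cell (full-grid vector or
#'   `eid_layer`).
#' @return A single cell index.
#' @export
draw_absence <- function(eligible, weight_layer) {
  if (length(eligible) == 0L) stop("no eligible background cells")
  w <- if (inherits(weight_layer, "eid_layer")) weight_layer$values
       else weight_layer
  w <- w[eligible]
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("background weights are all zero on eligible cells")
  if (length(eligible) == 1L) return(eligible)
  eligible[sample.int(length(eligible), 1L, prob = w)]
}

absence_weights <- function(grid, effort, mode) {
  if (mode == "weighted") effort$values else grid$cell_area
}

make_pairs <- function(events, idx, eligible, effort, grid, mode) {
  w_abs <- absence_weights(grid, effort, mode)
  data.frame(
    event_id = vapply(events[idx], `[[`, character(1), "id"),
    presence_cell = vapply(events[idx], draw_presence, integer(1),
                           effort = effort),
    absence_cell = vapply(idx, function(i) draw_absence(eligible, w_abs),
                          integer(1)),
    year = vapply(events[idx], `[[`, integer(1), "year"),
    stringsAsFactors = FALSE
  )
}

#' Draw one bootstrap replicate of presence/absence pairs
#'
#' Resamples the events with replacement (n out of n) and draws one presence
#' and one absence cell per draw, fixing prevalence at exactly 0.5. This is
#' the unit of the bootstrap ensemble: event resampling propagates sampling
#' uncertainty, footprint draws propagate geocoding uncertainty.
#'
#' @param events list of `eid_event`s.
#' @param effort effort `eid_layer`.
#' @param predictors `predictor_set` (defines eligible background cells).
#' @param config a `resampling_config`.
#' @return A data frame of sample pairs (`event_id`, `presence_cell`,
#'   `absence_cell`, `year`, `decade`).
#' @export
bootstrap_replicate <- function(events, effort, predictors, config) {
  stopifnot(length(events) > 0L)
  grid <- predictors$grid
  eligible <- which(complete_cells(predictors))
  idx <- sample.int(length(events), length(events), replace = TRUE)
  pairs <- make_pairs(events, idx, eligible, effort, grid, config$mode)
  pairs$decade <- match_decade(pairs$year)
  pairs
}

#' Assign events to cross-validation folds
#'
#' For each round, draws one presence/absence pair per event (no bootstrap)
#' and assigns pairs randomly to `k` near-equal folds (sizes differ by at
#' most 1). The presence and absence of a pair share a fold by default, so a
#' pair never straddles the train/test split.
#'
#' @param events list of `eid_event`s.
#' @param effort effort `eid_layer`.
#' @param predictors `predictor_set`.
#' @param config a `resampling_config` (its mode sets absence weights).
#' @param k folds (default 10).
#' @return A data frame of pairs with a `fold` column.
#' @export
cv_partition <- function(events, effort, predictors, config, k = 10L) {
  n <- length(events)
  if (k > n) stop(sprintf("k = %d folds but only %d events", k, n))
  grid <- predictors$grid
  eligible <- which(complete_cells(predictors))
  pairs <- make_pairs(events, seq_len(n), eligible, effort, grid,
                      config$mode)
  pairs$decade <- match_decade(pairs$year)
  pairs$fold <- sample(rep_len(seq_len(k), n))
  pairs
}

#' Assemble the model design matrix from sample pairs
#'
#' Two rows per pair (presence label 1, absence label 0). Each row resolves
#' every predictor at the sampled cell and the event's matched decade:
#' decadal predictors use the nearest decadal snapshot (years ending in 5
#' round up), change predictors use the decade interval ending at that
#' snapshot, static predictors (including reporting effort) ignore the year.
#'
#' @param pairs data frame from [bootstrap_replicate()] or [cv_partition()].
#' @param predictors `predictor_set`.
#' @return A list with `x` (numeric matrix, one column per predictor),
#'   `y` (0/1 labels), and `pairs` (row-aligned bookkeeping: `event_id`,
#'   `cell`, `role`, and `fold` when present).
#' @export
assemble_design <- function(pairs, predictors) {
  nms <- predictor_names(predictors)
  n <- nrow(pairs)
  cells <- c(pairs$presence_cell, pairs$absence_cell)
  years <- rep(pairs$year, 2L)
  y <- rep(c(1, 0), each = n)
  x <- matrix(NA_real_, 2L * n, length(nms), dimnames = list(NULL, nms))
  for (yr in unique(years)) {
    rows <- which(years == yr)
    for (nm in nms)
      x[rows, nm] <- get_layer(predictors, nm, yr)$values[cells[rows]]
  }
  if (anyNA(x))
    stop("internal error: sampled cell with missing predictor (ineligible cell drawn)")
  meta <- data.frame(event_id = rep(pairs$event_id, 2L), cell = cells,
                     role = rep(c("presence", "absence"), each = n),
                     stringsAsFactors = FALSE)
  if (!is.null(pairs$fold)) meta$fold <- rep(pairs$fold, 2L)
  list(x = x, y = y, pairs = meta)
}

#' Export sample pairs for audit
#'
#' Long-format CSV with explicit coordinates (`replicate, event_id, role,
#' lon, lat, decade`), one row per pair member.
#'
#' @param pairs pair data frame.
#' @param grid `grid_spec`.
#' @param path output CSV.
#' @param replicate replicate label.
#' @export
write_pairs_csv <- function(pairs, grid, path, replicate = 1L) {
  long <- data.frame(
    replicate = replicate,
    event_id = rep(pairs$event_id, 2L),
    role = rep(c("presence", "absence"), each = nrow(pairs)),
    lon = grid$lon[c(pairs$presence_cell, pairs$absence_cell)],
    lat = grid$lat[c(pairs$presence_cell, pairs$absence_cell)],
    decade = rep(pairs$decade, 2L))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
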