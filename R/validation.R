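#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' presence is scored above a randomly chosen absence, with ties credited
#' 0.5.
#'
#' @param labels 0/1 outcomes (both classes required).
#' @param scores numeric scores, same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("auc needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True Skill Statistic
#'
#' Maximum over candidate thresholds of sensitivity + specificity - 1, with
#' candidates taken exhaustively at the midpoints of consecutive sorted
#' unique scores (plus thresholds below and above every score). Scores at or
#' above the threshold are called presences.
#'
#' @param labels 0/1 outcomes (both classes required).
#' @param scores numeric scores, same length.
#' @return TSS in `[-1, 1]`; 0 when all scores are identical.
#' @export
tss <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("tss needs both classes")
  u <- sort(unique(scores))
  if (length(u) == 1L) return(0)
  thr <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  best <- -1
  for (t in thr) {
    pos <- scores >= t
    sens <- sum(pos & labels == 1) / n1
    spec <- sum(!pos & labels == 0) / n0
    best <- max(best, sens + spec - 1)
  }
  best
}

#' Percentage of Bernoulli deviance explained
#'
#' `100 * (1 - residual / null)` mean deviance, the boosted-tree analogue of
#' variance explained. The null prediction is the observed prevalence (0.5
#' under the paired resampling regime). For a weighted model the result is
#' relative to reporting effort, since the background sample already absorbs
#' that variable.
#'
#' @param fit a `brt_fit`.
#' @param design the training design (list with `x`, `y`); defaults to the
#'   deviances stored in the fit.
#' @return Percentage (can be negative for a worse-than-null fit).
#' @export
deviance_explained <- function(fit, design = NULL) {
  if (is.null(design)) {
    resid <- fit$training_deviance
    null <- fit$null_deviance
  } else {
    resid <- bernoulli_deviance(design$y, predict(fit, design$x))
    null <- bernoulli_deviance(design$y,
                               rep(mean(design$y), length(design$y)))
  }
  if (null == 0) stop("null deviance is zero")
  100 * (1 - resid / null)
}

#' Summarise per-round validation scores
#'
#' @param values numeric per-round scores.
#' @param metric metric name.
#' @return A `score_summary` with the median and empirical 0.05/0.95
#'   quantiles plus the raw per-round values.
#' @export
score_summary <- function(values, metric) {
  q <- stats::quantile(values, c(0.05, 0.5, 0.95), names = FALSE,
                       na.rm = TRUE)
  structure(list(metric = metric, median = q[2], q05 = q[1], q95 = q[3],
                 values = values),
            class = "score_summary")
}

#' @export
print.score_summary <- function(x, ...) {
  cat(sprintf("%s: median %.3f (90%% CI %.3f-%.3f) over %d rounds\n",
              x$metric, x$median, x$q05, x$q95, length(x$values)))
  invisible(x)
}

#' Repeated k-fold cross-validation of the event model
#'
#' The study's validation protocol: per round, one presence/absence pair is
#' drawn per event (absences weighted per the training mode), pairs are
#' assigned to k near-equal folds, each fold is held out in turn, and the
#' held-out predictions are pooled within the round into a single AUC and
#' TSS. Summaries are the median and empirical 90% CI over rounds.
#'
#' The held-out absences can be re-drawn under a different null than the
#' training absences (`null_mode`): evaluating a weighted model against an
#' unweighted (land-area) null gives the clearer contrast reported alongside
#' the weighted-null scores.
#'
#' @param events list of `eid_event`s.
#' @param predictors `predictor_set`.
#' @param effort effort `eid_layer`.
#' @param config `resampling_config` (its `mode` sets training absences).
#' @param boost `boost_config`.
#' @param null_mode `"weighted"` or `"unweighted"`: weighting of the
#'   held-out validation absences (defaults to the training mode).
#' @param rounds CV rounds (study default 100).
#' @param k folds per round (default 10).
#' @param seed RNG seed.
#' @param permute_labels if TRUE, pair labels are permuted within each round
#'   (cell roles swapped at random) — a null-calibration check that should
#'   return AUC near 0.5 and TSS near 0.
#' @return List of `score_summary` objects (`auc`, `tss`) plus a long
#'   per-round data frame `scores`.
#' @export
cross_validate <- function(events, predictors, effort, config,
                           boost = boost_config(), null_mode = config$mode,
                           rounds = 100L, k = 10L, seed = 1L,
                           permute_labels = FALSE) {
  set.seed(seed)
  grid <- predictors$grid
  eligible <- which(complete_cells(predictors))
  auc_r <- tss_r <- numeric(rounds)
  n_null <- 0L
  for (r in seq_len(rounds)) {
    gc(verbose = FALSE)  # release dead engine handles between rounds
    pairs <- cv_partition(events, effort, predictors, config, k = k)
    if (null_mode != config$mode) {
      w_val <- absence_weights(grid, effort, null_mode)
      pairs$val_absence_cell <- vapply(seq_len(nrow(pairs)), function(i)
        draw_absence(eligible, w_val), integer(1))
    } else {
      pairs$val_absence_cell <- pairs$absence_cell
    }
    if (permute_labels) {
      flip <- sample(c(TRUE, FALSE), nrow(pairs), replace = TRUE)
      tmp <- pairs$presence_cell[flip]
      pairs$presence_cell[flip] <- pairs$absence_cell[flip]
      pairs$absence_cell[flip] <- tmp
      # keep validation absences consistent with the permuted training roles
      if (null_mode == config$mode) pairs$val_absence_cell <- pairs$absence_cell
    }
    y_all <- score_all <- numeric(0)
    for (f in seq_len(k)) {
      train <- pairs[pairs$fold != f, , drop = FALSE]
      test <- pairs[pairs$fold == f, , drop = FALSE]
      # null fits (failed gradient descent) predict the prevalence and are
      # counted rather than warned about round by round
      fit <- suppressWarnings(fit_step(assemble_design(train, predictors),
                                       boost))
      n_null <- n_null + fit$null_model
      test_val <- test
      test_val$absence_cell <- test_val$val_absence_cell
      dtest <- assemble_design(test_val, predictors)
      y_all <- c(y_all, dtest$y)
      score_all <- c(score_all, predict(fit, dtest$x))
    }
    auc_r[r] <- auc(y_all, score_all)
    tss_r[r] <- tss(y_all, score_all)
  }
  scores <- data.frame(round = rep(seq_len(rounds), 2L),
                       metric = rep(c("auc", "tss"), each = rounds),
                       value = c(auc_r, tss_r))
  list(auc = score_summary(auc_r, "auc"), tss = score_summary(tss_r, "tss"),
       scores = scores, n_null_fits = n_null)
}

#' Write per-round validation scores and their summary
#'
#' @param cv result of [cross_validate()].
#' @param csv_path per-round scores CSV (`round, metric, value`).
#' @param json_path JSON summary (median / q05 / q95 per metric).
#' @export
write_scores <- function(cv, csv_path, json_path) {
  utils::write.csv(cv$scores, csv_path, row.names = FALSE)
  s <- lapply(cv[c("auc", "tss")], function(x)
    list(median = x$median, q05 = x$q05, q95 = x$q95))
  jsonlite::write_json(s, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
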