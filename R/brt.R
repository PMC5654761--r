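#' Boosted-regression-tree configuration
#'
#' Hyperparameters of the stagewise Bernoulli boosting used for the event
#' models. The study configuration is `tree_complexity = 3` (interaction
#' depth), `learning_rate = 0.0035` (shrinkage) and `step_size = 35` (initial
#' trees and per-step increment), with the tree count chosen by internal
#' 10-fold CV deviance; those are the defaults here. Simulation studies on
#' coarse grids use a larger learning rate (see the methods vignette).
#'
#' @param tree_complexity maximum tree depth.
#' @param learning_rate shrinkage applied to each tree.
#' @param step_size trees added per stagewise step; the selected tree count
#'   is always a multiple of this.
#' @param internal_cv_folds folds for the internal CV deviance trajectory.
#' @param max_trees hard cap on trees explored.
#' @param patience stagewise stopping: stop once the CV minimum has not
#'   improved for this many steps.
#' @param bag_fraction row subsample rate per tree (stochastic boosting).
#' @param max_bin histogram bins per feature in the tree builder; small
#'   designs lose nothing from coarse binning and train much faster.
#' @return A `boost_config` list.
#' @export
boost_config <- function(tree_complexity = 3L, learning_rate = 0.0035,
                         step_size = 35L, internal_cv_folds = 10L,
                         max_trees = 10000L, patience = 3L,
                         bag_fraction = 0.75, max_bin = 256L) {
  stopifnot(tree_complexity >= 1L, learning_rate > 0, learning_rate <= 1,
            step_size >= 1L, internal_cv_folds >= 2L, max_trees >= step_size,
            patience >= 1L, bag_fraction > 0, bag_fraction <= 1,
            max_bin >= 2L)
  structure(list(tree_complexity = as.integer(tree_complexity),
                 learning_rate = learning_rate,
                 step_size = as.integer(step_size),
                 internal_cv_folds = as.integer(internal_cv_folds),
                 max_trees = as.integer(max_trees),
                 patience = as.integer(patience),
                 bag_fraction = bag_fraction,
                 max_bin = as.integer(max_bin)),
            class = "boost_config")
}

#' Boosting configuration for the synthetic simulation studies
#'
#' On the 40 x 20 synthetic worlds (294-row bootstrap designs) the
#' cross-validated tree optimum sits around 100-300 trees at shrinkage
#' 0.015, so the stagewise minimum is interior at 35-tree steps; 5 internal
#' folds and coarse 32-bin histograms keep a full bootstrap ensemble fast
#' without changing the selected models appreciably. See the methods
#' vignette.
#'
#' @param ... overrides passed to [boost_config()].
#' @return A `boost_config`.
#' @export
sim_boost_config <- function(...) {
  args <- list(learning_rate = 0.015, internal_cv_folds = 5L,
               max_trees = 3000L, patience = 4L, max_bin = 32L)
  over <- list(...)
  args[names(over)] <- over
  do.call(boost_config, args)
}

#' Mean Bernoulli deviance
#'
#' `-2 * mean(y * log(p) + (1 - y) * log(1 - p))`, with probabilities clamped
#' to `[1e-9, 1 - 1e-9]`. The null model predicting 0.5 everywhere scores
#' `2 * log(2)`.
#'
#' @param labels 0/1 outcomes.
#' @param probs predicted probabilities, same length.
#' @return Nonnegative mean deviance.
#' @export
bernoulli_deviance <- function(labels, probs) {
  if (length(labels) == 0L) stop("empty input")
  stopifnot(length(labels) == length(probs), all(labels %in% c(0, 1)))
  p <- pmin(1 - 1e-9, pmax(1e-9, probs))
  -2 * mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# stratified fold labels preserving class balance
stratified_folds <- function(y, k) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    f[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  f
}

xgb_params <- function(config, objective = "binary:logistic", seed = 0L) {
  list(objective = objective, max_depth = config$tree_complexity,
       eta = config$learning_rate, subsample = config$bag_fraction,
       max_bin = config$max_bin, base_score = 0.5, nthread = 1, seed = seed)
}

# extend an xgboost handle by `add` rounds (stagewise continuation)
extend_model <- function(model, dtrain, params, add) {
  xgboost::xgb.train(params, dtrain, nrounds = add, verbose = 0,
                     xgb_model = model)
}

predict_prefix <- function(model, x, n_trees) {
  # iterationrange is base-1 and inclusive: trees 1..n_trees
  predict(model, x, iterationrange = c(1, n_trees))
}

#' Fit a boosted-tree model with stagewise CV tree selection
#'
#' Fits `step_size` trees, then repeatedly adds `step_size` more while the
#' internal k-fold CV mean Bernoulli deviance keeps improving (stopping once
#' the running minimum has not improved for `patience` steps or `max_trees`
#' is reached), and selects the tree count minimising CV deviance. Because
#' boosting is stagewise, trees are trained in larger chunks and evaluated
#' at every step-multiple prefix — numerically identical to literal
#' increments, with fewer engine calls.
#'
#' If the CV deviance never drops below the null (intercept-only) deviance
#' the gradient descent has failed at step 1; the fit is flagged as a null
#' model (predicting the observed prevalence) and a warning is raised.
#'
#' @param design list with matrix `x` and 0/1 vector `y`
#'   (from [assemble_design()]).
#' @param config a [boost_config()].
#' @return An object of class `brt_fit`: `n_trees_selected`,
#'   `cv_deviance_trajectory` (per step), `null_deviance`,
#'   `training_deviance`, `null_model` flag, the engine handle and the
#'   training feature names.
#' @export
fit_step <- function(design, config = boost_config()) {
  x <- design$x; y <- design$y
  stopifnot(is.matrix(x), length(y) == nrow(x))
  if (length(unique(y)) < 2L) stop("design must contain both classes")
  if (nrow(x) < 2L * config$internal_cv_folds)
    stop("too few rows for the internal CV folds")
  k <- config$internal_cv_folds
  step <- config$step_size
  engine_seed <- sample.int(.Machine$integer.max, 1L)
  params <- xgb_params(config, seed = engine_seed)
  folds <- stratified_folds(y, k)
  dfold <- lapply(seq_len(k), function(f)
    xgboost::xgb.DMatrix(x[folds != f, , drop = FALSE],
                         label = y[folds != f]))
  dfull <- xgboost::xgb.DMatrix(x, label = y)
  null_dev <- bernoulli_deviance(y, rep(mean(y), length(y)))

  chunk_steps <- config$patience + 2L
  fold_models <- vector("list", k)
  full_model <- NULL
  trained <- 0L
  traj <- numeric(0)
  cv_pred <- rep(NA_real_, length(y))
  repeat {
    target <- min(trained + chunk_steps * step, config$max_trees)
    add <- target - trained
    if (add <= 0L) break
    for (f in seq_len(k))
      fold_models[[f]] <- extend_model(fold_models[[f]], dfold[[f]], params, add)
    full_model <- extend_model(full_model, dfull, params, add)
    new_steps <- seq.int(trained + step, target, by = step)
    stop_now <- FALSE
    for (s in new_steps) {
      for (f in seq_len(k)) {
        ho <- folds == f
        cv_pred[ho] <- predict_prefix(fold_models[[f]],
                                      x[ho, , drop = FALSE], s)
      }
      traj <- c(traj, bernoulli_deviance(y, cv_pred))
      if (length(traj) - which.min(traj) >= config$patience) {
        stop_now <- TRUE
        break
      }
    }
    trained <- target
    if (stop_now || trained >= config$max_trees) break
  }

  best <- which.min(traj)
  n_sel <- best * step
  null_model <- traj[best] >= null_dev - 1e-12
  if (null_model)
    warning("CV deviance never improved on the null model; returning null fit")
  train_pred <- if (null_model) rep(mean(y), length(y))
                else predict_prefix(full_model, x, n_sel)
  structure(list(model = full_model,
                 n_trees_selected = if (null_model) 0L else n_sel,
                 cv_deviance_trajectory = traj,
                 null_deviance = null_dev,
                 cv_deviance = traj[best],
                 training_deviance = bernoulli_deviance(y, train_pred),
                 null_model = null_model,
                 prevalence = mean(y),
                 feature_names = colnames(x),
                 config = config),
            class = "brt_fit")
}

#' @export
print.brt_fit <- function(x, ...) {
  if (x$null_model) {
    cat("<brt_fit> null model (CV deviance never beat the null)\n")
  } else {
    cat(sprintf("<brt_fit> %d trees (CV dev %.4f, null %.4f, train %.4f)\n",
                x$n_trees_selected, x$cv_deviance, x$null_deviance,
                x$training_deviance))
  }
  invisible(x)
}

#' Predict event probabilities from a fitted BRT
#'
#' @param object a `brt_fit`.
#' @param newdata numeric matrix with the training columns (checked by name).
#' @param ... unused.
#' @return Probabilities in (0, 1), deterministic given the fit. A null
#'   model predicts the training prevalence everywhere.
#' @export
predict.brt_fit <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (!identical(colnames(newdata), object$feature_names)) {
    if (is.null(colnames(newdata)) ||
        !all(object$feature_names %in% colnames(newdata)))
      stop("newdata does not carry the training predictor set")
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  if (object$null_model) return(rep(object$prevalence, nrow(newdata)))
  predict_prefix(object$model, newdata, object$n_trees_selected)
}

#' Relative influence of each predictor
#'
#' Per-predictor share of the total split improvement (loss reduction summed
#' over every split on that predictor across the selected trees), normalised
#' to sum to 100. Predictors never split on score exactly 0.
#'
#' @param fit a `brt_fit`.
#' @return Named numeric vector over all training predictors, summing to 100
#'   (all zero for a null model).
#' @export
relative_influence <- function(fit) {
  out <- stats::setNames(numeric(length(fit$feature_names)),
                         fit$feature_names)
  if (fit$null_model || fit$n_trees_selected == 0L) return(out)
  # parse the engine's text dump: per-split lines look like
  #   1:[feature<split] yes=..,no=..,missing=..,gain=G,cover=C
  dump <- xgboost::xgb.dump(fit$model, with_stats = TRUE)
  tree_id <- cumsum(startsWith(dump, "booster[")) - 1L
  keep <- tree_id < fit$n_trees_selected & grepl("gain=", dump, fixed = TRUE)
  lines <- dump[keep]
  if (length(lines) == 0L) return(out)
  a <- regexpr("[", lines, fixed = TRUE)
  b <- regexpr("<", lines, fixed = TRUE)
  feat <- substr(lines, a + 1L, b - 1L)
  gpos <- regexpr("gain=", lines, fixed = TRUE)
  gain <- as.numeric(sub(",.*$", "",
                         substr(lines, gpos + 5L, nchar(lines)),
                         perl = TRUE))
  gains <- tapply(gain, feat, sum)
  out[names(gains)] <- as.numeric(gains)
  100 * out / sum(out)
}

#' Partial dependence of the fitted response on one predictor
#'
#' For each probe value v, the mean prediction over the training rows with
#' the target column replaced by v — the model's marginal response holding
#' all other predictors at their observed values. The default probe grid
#' spans the 10th-90th percentile of the training values.
#'
#' @param fit a `brt_fit`.
#' @param predictor predictor name.
#' @param train_x the training matrix (rows to average over).
#' @param probe_values explicit probe grid; default `n_probe` points from
#'   the 10th to the 90th percentile of `train_x[, predictor]`.
#' @param n_probe default grid size.
#' @return Data frame with columns `value` and `yhat`.
#' @export
partial_dependence <- function(fit, predictor, train_x, probe_values = NULL,
                               n_probe = 25L) {
  if (!(predictor %in% fit$feature_names))
    stop(sprintf("'%s' is not a model predictor", predictor))
  stopifnot(is.matrix(train_x),
            identical(colnames(train_x), fit$feature_names))
  if (is.null(probe_values)) {
    q <- stats::quantile(train_x[, predictor], c(0.1, 0.9), names = FALSE)
    probe_values <- seq(q[1], q[2], length.out = n_probe)
  }
  n <- nrow(train_x)
  big <- train_x[rep(seq_len(n), times = length(probe_values)), ,
                 drop = FALSE]
  big[, predictor] <- rep(probe_values, each = n)
  pred <- predict(fit, big)
  data.frame(value = probe_values,
             yhat = as.numeric(tapply(pred, rep(seq_along(probe_values),
                                                each = n), mean)))
}
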