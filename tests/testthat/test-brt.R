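# deterministic toy designs for engine-level checks
toy_design <- function(n = 300, p = 6, signal = 2, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  prob <- stats::plogis(signal * x[, 1])
  list(x = x, y = stats::rbinom(n, 1, prob))
}

test_that("Bernoulli deviance matches closed forms and a summation oracle", {
  y <- c(1, 1, 0, 0)
  # p = 0.5 everywhere: 2 log 2
  expect_equal(bernoulli_deviance(y, rep(0.5, 4)), 2 * log(2))
  # near-perfect probabilities: ~ 0
  expect_lt(bernoulli_deviance(y, c(1, 1, 0, 0)), 1e-7)
  # random case vs per-sample summation
  set.seed(5)
  yy <- rbinom(50, 1, 0.5)
  pp <- runif(50, 0.01, 0.99)
  expect_equal(bernoulli_deviance(yy, pp),
               -2 * sum(yy * log(pp) + (1 - yy) * log(1 - pp)) / 50)
  expect_error(bernoulli_deviance(numeric(0), numeric(0)), "empty")
})

test_that("stagewise fitting selects trees by CV and is seed-reproducible", {
  d <- toy_design()
  set.seed(10)
  f <- fit_step(d, fast_boost())
  expect_false(f$null_model)
  expect_identical(f$n_trees_selected %% f$config$step_size, 0L)
  expect_gte(f$n_trees_selected, f$config$step_size)
  # CV deviance strictly below the null for a separable signal
  expect_lt(f$cv_deviance, f$null_deviance)
  # trajectory minimum is where the selection says it is
  expect_identical(f$n_trees_selected,
                   which.min(f$cv_deviance_trajectory) *
                     f$config$step_size)
  # same seed and design: identical selection and predictions
  set.seed(10)
  f2 <- fit_step(d, fast_boost())
  expect_identical(f2$n_trees_selected, f$n_trees_selected)
  expect_equal(predict(f2, d$x), predict(f, d$x))

  # pure-noise labels: deviance explained ~ 0 (within 0.05 at n = 300)
  set.seed(11)
  dn <- list(x = d$x, y = sample(d$y))
  fn <- suppressWarnings(fit_step(dn, fast_boost()))
  expect_lt(abs(deviance_explained(fn)) , 100 * 0.05 + 1e-9)

  expect_error(fit_step(list(x = d$x, y = rep(1, 300)), fast_boost()),
               "both classes")
})

test_that("predictions are probabilities, deterministic, and monotone in a
           monotone signal", {
  d <- toy_design(signal = 3)
  set.seed(20)
  f <- fit_step(d, fast_boost())
  pr <- predict(f, d$x)
  expect_true(all(pr > 0 & pr < 1))
  # training predictions reproduce the stored training deviance
  expect_equal(bernoulli_deviance(d$y, pr), f$training_deviance)
  # duplicated rows predict identically
  expect_equal(predict(f, d$x[c(1, 1, 2), ]), pr[c(1, 1, 2)])
  # monotone univariate signal: predictions rise across probe quantiles
  probe <- d$x[rep(1, 9), , drop = FALSE]
  probe[, "v1"] <- quantile(d$x[, "v1"], seq(0.1, 0.9, by = 0.1))
  pp <- predict(f, probe)
  expect_gt(cor(pp, seq_len(9), method = "spearman"), 0.9)
  # unseen predictor set is rejected
  bad <- d$x; colnames(bad) <- paste0("w", 1:6)
  expect_error(predict(f, bad), "predictor set")
})

test_that("relative influence sums to 100 and finds the only active driver", {
  # outcome depends only on x1 among 11 predictors at n = 500
  set.seed(30)
  x <- matrix(rnorm(500 * 11), 500, 11,
              dimnames = list(NULL, paste0("x", 1:11)))
  y <- rbinom(500, 1, stats::plogis(2.5 * x[, 1]))
  f <- fit_step(list(x = x, y = y), fast_boost())
  ri <- relative_influence(f)
  expect_equal(sum(ri), 100)
  expect_identical(names(which.max(ri)), "x1")
  expect_gt(ri[["x1"]], 50)

  # a predictor never split on scores exactly 0: force one constant column
  x2 <- cbind(x, dead = 0)
  set.seed(31)
  f2 <- fit_step(list(x = x2, y = y), fast_boost())
  expect_identical(relative_influence(f2)[["dead"]], 0)
})

test_that("partial dependence equals the column-replacement oracle", {
  d <- toy_design(n = 200, signal = 2)
  set.seed(40)
  f <- fit_step(d, fast_boost())
  probes <- quantile(d$x[, "v2"], c(0.2, 0.5, 0.8), names = FALSE)
  pd <- partial_dependence(f, "v2", d$x, probe_values = probes)
  # brute force: replace the column row by row and average
  for (j in seq_along(probes)) {
    xm <- d$x
    xm[, "v2"] <- probes[j]
    expect_equal(pd$yhat[j], mean(predict(f, xm)))
  }
  # default probe grid spans the 10th-90th percentile
  pd2 <- partial_dependence(f, "v1", d$x, n_probe = 7)
  expect_equal(range(pd2$value),
               as.numeric(quantile(d$x[, "v1"], c(0.1, 0.9))))
  # y independent of v3: flat curve within a noise band
  pd3 <- partial_dependence(f, "v3", d$x)
  expect_lt(diff(range(pd3$yhat)), 0.2)
  expect_error(partial_dependence(f, "zz", d$x), "not a model predictor")
})

test_that("deviance explained is complement-invariant and label-symmetric", {
  d <- toy_design(n = 300, signal = 2, seed = 17)
  set.seed(50)
  f <- fit_step(d, fast_boost())
  de <- deviance_explained(f)
  expect_gt(de, 0)
  # closed form from the deviance components
  expect_equal(de, 100 * (1 - f$training_deviance / f$null_deviance))
  # relabelling 0<->1 with complemented probabilities leaves it unchanged
  pr <- predict(f, d$x)
  resid_flip <- bernoulli_deviance(1 - d$y, 1 - pr)
  null_flip <- bernoulli_deviance(1 - d$y,
                                  rep(mean(1 - d$y), length(d$y)))
  expect_equal(100 * (1 - resid_flip / null_flip), de)
  # predictions at prevalence: exactly 0%
  null_fit <- f
  null_fit$training_deviance <- null_fit$null_deviance
  expect_equal(deviance_explained(null_fit), 0)
})
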