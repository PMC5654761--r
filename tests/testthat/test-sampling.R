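test_that("presence draws follow effort weights over the footprint", {
  g <- flat_grid()
  eff <- layer("reporting_effort", rep(1, 32), g)

  # single-cell footprint: that cell with probability 1
  ev1 <- eid_event("e1", 1990L, 5L)
  expect_identical(draw_presence(ev1, eff), 5L)

  # footprint {A: 3, B: 1}: frequency of A within 3 sigma of 0.75
  eff$values[5] <- 3; eff$values[6] <- 1
  ev2 <- eid_event("e2", 1990L, c(5L, 6L))
  set.seed(52)
  draws <- replicate(10000, draw_presence(ev2, eff))
  p <- mean(draws == 5L)
  expect_lt(abs(p - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))

  # all-zero-effort footprint: documented uniform fallback
  eff0 <- layer("reporting_effort", rep(0, 32), g)
  set.seed(53)
  d0 <- replicate(2000, draw_presence(ev2, eff0))
  expect_lt(abs(mean(d0 == 5L) - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("absence draws respect the weight layer", {
  g <- flat_grid()
  # two eligible cells, equal weights: 50/50 within 3 sigma
  set.seed(61)
  d <- replicate(10000, draw_absence(c(3L, 9L), rep(1, 32)))
  expect_lt(abs(mean(d == 3L) - 0.5), 3 * sqrt(0.25 / 10000))

  # concentrated weight: always that cell
  w <- rep(0, 32); w[7] <- 5
  expect_true(all(replicate(50, draw_absence(c(3L, 7L, 9L), w)) == 7L))

  # chi-square goodness of fit on 100 random weights at 1e5 draws
  g2 <- grid_spec(20L, 5L)
  set.seed(62)
  wts <- rexp(100) + 0.05
  cells <- seq_len(100)
  draws <- replicate(1e5, draw_absence(cells, c(wts, rep(0, 0))))
  obs <- tabulate(draws, nbins = 100)
  expect_gt(stats::chisq.test(obs, p = wts / sum(wts))$p.value, 0.001)

  expect_error(draw_absence(integer(0), rep(1, 32)), "no eligible")
  expect_error(draw_absence(c(1L, 2L), rep(0, 32)), "all zero")
})

test_that("bootstrap replicates fix prevalence at exactly 0.5 and reproduce", {
  w <- small_world()
  cfg <- resampling_config(n_replicates = 1, mode = "weighted")
  set.seed(71)
  pairs <- bootstrap_replicate(w$events, w$effort$smoothed, w$predictors,
                               cfg)
  expect_identical(nrow(pairs), length(w$events))
  d <- assemble_design(pairs, w$predictors)
  expect_equal(mean(d$y), 0.5)
  expect_identical(dim(d$x), c(2L * nrow(pairs), 20L))

  # same seed, identical replicate
  set.seed(72)
  p1 <- bootstrap_replicate(w$events, w$effort$smoothed, w$predictors, cfg)
  set.seed(72)
  p2 <- bootstrap_replicate(w$events, w$effort$smoothed, w$predictors, cfg)
  expect_identical(p1, p2)

  # unique-event fraction over replicates near 1 - (1 - 1/n)^n
  set.seed(73)
  n <- length(w$events)
  fr <- replicate(300, {
    p <- bootstrap_replicate(w$events, w$effort$smoothed, w$predictors, cfg)
    length(unique(p$event_id)) / n
  })
  expect_lt(abs(mean(fr) - (1 - (1 - 1 / n)^n)), 0.02)
})

test_that("CV partitions are near-equal, exhaustive, and pair-coherent", {
  w <- default_world()
  cfg <- resampling_config(mode = "weighted")
  set.seed(81)
  pairs <- cv_partition(w$events, w$effort$smoothed, w$predictors, cfg,
                        k = 10L)
  sizes <- table(pairs$fold)
  expect_lte(diff(range(sizes)), 1)
  # 147 events into 10 folds: seven folds of 15 and three of 14
  expect_identical(sort(as.integer(sizes)), c(rep(14L, 3), rep(15L, 7)))
  # every pair held out exactly once
  expect_identical(sort(unlist(lapply(1:10, function(f)
    which(pairs$fold == f)))), seq_len(147))
  expect_error(cv_partition(w$events[1:5], w$effort$smoothed, w$predictors,
                            cfg, k = 10L), "folds but only")
})

test_that("designs resolve decadal and change layers at the event year", {
  w <- small_world()
  ps <- w$predictors
  cfg <- resampling_config(mode = "weighted")
  set.seed(91)
  pairs <- bootstrap_replicate(w$events, w$effort$smoothed, ps, cfg)
  d <- assemble_design(pairs, ps)
  # spot-check 10 random rows against direct layer lookups
  set.seed(92)
  rows <- sample(nrow(d$x), 10)
  n <- nrow(pairs)
  for (r in rows) {
    pair_i <- if (r <= n) r else r - n
    cell <- if (r <= n) pairs$presence_cell[pair_i] else
      pairs$absence_cell[pair_i]
    yr <- pairs$year[pair_i]
    for (nm in c("evergreen_broadleaf", "human_population",
                 "pasture_change", "reporting_effort"))
      expect_identical(unname(d$x[r, nm]),
                       get_layer(ps, nm, yr)$values[cell])
  }
  # a 1975 event uses the 1980 snapshot
  p75 <- pairs[1, ]
  p75$year <- 1975L
  d75 <- assemble_design(p75, ps)
  expect_identical(unname(d75$x[1, "human_population"]),
                   get_layer(ps, "human_population", 1980L)$values[
                     p75$presence_cell])

  # weighted vs unweighted modes differ only in absence weights: with the
  # same RNG state the resampled event sequence and presence draws agree
  set.seed(93)
  pw <- bootstrap_replicate(w$events, w$effort$smoothed, ps,
                            resampling_config(mode = "weighted"))
  set.seed(93)
  pu <- bootstrap_replicate(w$events, w$effort$smoothed, ps,
                            resampling_config(mode = "unweighted"))
  expect_identical(pw$event_id, pu$event_id)
  expect_identical(pw$presence_cell, pu$presence_cell)
  # and any-mode designs keep prevalence exactly 0.5
  expect_equal(mean(assemble_design(pu, ps)$y), 0.5)
})
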