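test_that("generated predictors have the expected temporal structure", {
  w <- small_world()
  ps <- w$predictors
  # 20 predictors: 13 static (incl. reporting effort), 4 decadal, 3 change
  expect_length(predictor_names(ps), 20)
  expect_length(ps$decadal, 4)
  expect_length(ps$change, 3)
  for (nm in names(ps$decadal))
    expect_identical(sort(as.integer(names(ps$decadal[[nm]]))),
                     c(1970L, 1980L, 1990L, 2000L))

  # percentage layers live in [0, 100]
  for (nm in c("urban", "evergreen_broadleaf", "shrubs"))
    expect_true(all(get_layer(ps, nm, 2000L)$values >= 0 &
                      get_layer(ps, nm, 2000L)$values <= 100))

  # spatial autocorrelation: east-west neighbour correlation positive
  for (nm in c("gens", "mammal_richness", "human_population")) {
    v <- matrix(get_layer(ps, nm, 2000L)$values, nrow = w$grid$n_lat,
                byrow = TRUE)
    expect_gt(cor(as.numeric(v[, -1]), as.numeric(v[, -ncol(v)])), 0.3)
  }

  # change layers are non-trivial
  expect_gt(stats::sd(get_layer(ps, "pasture_change", 2000L)$values), 0)
})

test_that("urban land tracks population at the configured correlation", {
  # rank correlation target 0.7 (tolerance 0.15), averaged over seeds
  cors <- vapply(1:3, function(s) {
    w <- gen_world(synth_config(seed = 300 + s))
    land <- w$grid$land_mask
    cor(get_layer(w$predictors, "urban", 2000L)$values[land],
        get_layer(w$predictors, "human_population", 2000L)$values[land],
        method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.7), 0.15)
})

test_that("true risk is the advertised logistic and recomputes from metadata", {
  w <- small_world()
  land <- w$grid$land_mask
  expect_true(all(w$true_risk$values[land] > 0 &
                    w$true_risk$values[land] < 1))
  expect_true(all(is.na(w$true_risk$values[!land])))

  # bitwise recomputation from stored metadata
  eta <- rep(w$metadata$intercept, length(land))
  for (nm in names(w$metadata$drivers)) {
    mt <- w$metadata$drivers[[nm]]
    v <- get_layer(w$predictors, nm, 2000L)$values
    eta <- eta + mt$beta * (v - mt$mean) / mt$sd
  }
  expect_identical(stats::plogis(eta)[land], w$true_risk$values[land])

  # all-zero coefficients give a constant surface
  cfg0 <- synth_config(n_lon = 16L, n_lat = 8L,
                       drivers = c(evergreen_broadleaf = 0), seed = 77,
                       n_articles = 60L)
  set.seed(77)
  g0 <- grid_spec(16L, 8L, land_mask = rep(TRUE, 128))
  p0 <- gen_predictors(cfg0, g0)
  r0 <- gen_true_risk(p0, cfg0)
  expect_equal(unique(r0$risk$values), stats::plogis(cfg0$intercept))
  # unknown driver names are rejected
  expect_error(gen_true_risk(p0, synth_config(drivers = c(bogus = 1))),
               "unknown predictor")
})

test_that("the effort surface is urban-skewed and round-trips its matches", {
  w <- small_world()
  land <- w$grid$land_mask
  eff <- w$effort$smoothed$values
  urb <- get_layer(w$predictors, "urban", 2000L)$values
  expect_gt(cor(eff[land], urb[land], method = "spearman"), 0.5)
  # aggregate of the emitted match table reproduces the raw layer
  again <- aggregate_matches(w$matches, w$grid)
  expect_equal(again$values, w$effort$raw$values)
})

test_that("events follow risk-times-effort sampling with honest footprints", {
  w <- small_world()
  # all footprints on land
  for (e in w$events)
    expect_true(all(w$grid$land_mask[e$footprint]))
  # precise events are single-cell, imprecise ones are blocks
  precise <- vapply(w$events, `[[`, logical(1), "precise")
  sizes <- lengths(lapply(w$events, `[[`, "footprint"))
  expect_true(all(sizes[precise] == 1L))
  expect_true(any(sizes[!precise] > 1L))

  # footprint_precision 1 gives only single-cell footprints
  w1 <- gen_world(synth_config(n_lon = 16L, n_lat = 8L, n_events = 30L,
                               footprint_precision = 1, seed = 55,
                               n_articles = 60L))
  expect_true(all(lengths(lapply(w1$events, `[[`, "footprint")) == 1L))

  # fixed seed reproduces the event list exactly
  w2 <- gen_world(synth_config(n_lon = 16L, n_lat = 8L, n_events = 30L,
                               footprint_precision = 1, seed = 55,
                               n_articles = 60L))
  expect_identical(w1$events, w2$events)

  # bias_strength 0: event cells proportional to true risk alone
  # (chi-square frequency test at 10^4 events)
  cfg <- synth_config(n_lon = 16L, n_lat = 8L, n_events = 10000L,
                      bias_strength = 0, footprint_precision = 1,
                      seed = 56, n_articles = 60L)
  wb <- gen_world(cfg)
  land_idx <- which(wb$grid$land_mask)
  cells <- vapply(wb$events, function(e) e$footprint[1], integer(1))
  obs <- tabulate(match(cells, land_idx), nbins = length(land_idx))
  pr <- wb$true_risk$values[land_idx]
  p_chi <- suppressWarnings(
    stats::chisq.test(obs, p = pr / sum(pr))$p.value)
  expect_gt(p_chi, 0.001)
})

test_that("worlds serialise to plain text completely", {
  w <- small_world()
  dir <- withr::local_tempdir()
  write_world(w, dir)
  expect_true(all(file.exists(file.path(dir,
    c("predictors.csv", "surfaces.csv", "matches.csv", "events.geojson",
      "metadata.json")))))
  back <- read_layers_csv(file.path(dir, "surfaces.csv"), w$grid)
  nm <- vapply(back, `[[`, character(1), "name")
  tr <- back[[which(nm == "true_risk")]]
  expect_identical(tr$values, w$true_risk$values)
})
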