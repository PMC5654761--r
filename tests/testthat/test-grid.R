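test_that("block aggregation matches a nested-loop oracle and conserves sums", {
  # 2x2 block example
  g1 <- grid_spec(1L, 1L)
  fine <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(rescale_to_grid(fine, g1, "sum")$values, 10)
  expect_equal(rescale_to_grid(fine, g1, "mean")$values, 2.5)

  # identity at native resolution
  g <- flat_grid(6L, 3L)
  native <- matrix(rnorm(18), 3, 6)
  expect_equal(rescale_to_grid(native, g, "mean")$values,
               as.numeric(t(native)))

  # random fine field vs brute-force block loop
  set.seed(4)
  f <- 4L
  fine <- matrix(rnorm(3 * f * 6 * f), 3 * f, 6 * f)
  fine[sample(length(fine), 20)] <- NA
  for (method in c("sum", "mean")) {
    got <- rescale_to_grid(fine, g, method)$values
    oracle <- numeric(18)
    for (i in 1:3) for (j in 1:6) {
      b <- fine[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)]
      oracle[(i - 1) * 6 + j] <- if (method == "sum") sum(b, na.rm = TRUE)
                                 else mean(b, na.rm = TRUE)
    }
    expect_equal(got, oracle)
  }
  # conservation: sum-rescaling preserves the global total exactly
  expect_equal(sum(rescale_to_grid(fine, g, "sum")$values),
               sum(fine, na.rm = TRUE))

  # non-integer refinement is rejected
  expect_error(rescale_to_grid(matrix(0, 5, 7), g, "sum"),
               "integer refinement")
})

test_that("decade differencing is elementwise and validates its inputs", {
  g <- flat_grid()
  a <- layer("pasture", rep(0.30, 32), g, decade = 1990L)
  b <- layer("pasture", rep(0.42, 32), g, decade = 2000L)
  ch <- diff_decades(b, a)
  expect_equal(ch$values, rep(0.12, 32))
  expect_equal(ch$decade, c(1990L, 2000L))
  expect_equal(ch$name, "pasture_change")

  # identical layers give a zero change layer
  expect_equal(diff_decades(layer("x", 1:32 / 7, g, decade = 1980L),
                            layer("x", 1:32 / 7, g, decade = 1970L))$values,
               rep(0, 32))

  # random layers vs direct subtraction
  set.seed(9)
  v1 <- rnorm(32); v2 <- rnorm(32)
  expect_equal(diff_decades(layer("z", v2, g, decade = 1980L),
                            layer("z", v1, g, decade = 1970L))$values,
               v2 - v1)

  expect_error(diff_decades(b, layer("cropland", rep(0, 32), g,
                                     decade = 1990L)),
               "cannot difference")
  expect_error(diff_decades(b, layer("pasture", rep(0, 32), g,
                                     decade = 1970L)),
               "not consecutive")
})

test_that("decade matching rounds ties up, clamps post-2000, rejects pre-1970", {
  expect_identical(match_decade(1975L), 1980L)
  expect_identical(match_decade(1970L), 1970L)
  expect_error(match_decade(1969L), "before 1970")

  # exhaustive oracle: nearest decade, ties up, clamp at 2000
  decades <- c(1970L, 1980L, 1990L, 2000L)
  for (y in 1970:2008) {
    d <- abs(decades - y)
    cand <- decades[d == min(d)]
    expect_identical(match_decade(y), min(2000L, max(cand)),
                     label = paste("year", y))
  }
  # idempotent on decade years
  expect_identical(match_decade(decades), decades)
})

test_that("cell areas follow the spherical band formula", {
  # quadrature oracle for the [0, 1] degree band at 1-degree width
  f <- function(phi) (6371^2) * (pi / 180) * cos(phi * pi / 180) * (pi / 180)
  quad <- stats::integrate(f, 0, 1, rel.tol = 1e-12)$value
  expect_equal(band_area_km2(0, 1, 1), quad, tolerance = 1e-10)

  # strictly decreasing toward the poles, and N/S symmetric
  a <- band_area_km2(0:89, 1:90, 1)
  expect_true(all(diff(a) < 0))
  expect_equal(band_area_km2(-30, -29, 1), band_area_km2(29, 30, 1))

  # grid total equals the sphere's surface
  g <- grid_spec(36L, 18L)
  expect_equal(sum(g$cell_area), 4 * pi * 6371^2, tolerance = 1e-9)

  # land area within 1% of the mask's analytic sphere fraction (exact here
  # because the mask is made of whole cells)
  set.seed(2)
  mask <- runif(36 * 18) < 0.5
  mask[1] <- TRUE
  gm <- grid_spec(36L, 18L, land_mask = mask)
  expect_equal(sum(gm$cell_area[gm$land_mask]),
               sum(gm$cell_area * gm$land_mask), tolerance = 0.01)
})

test_that("headcount summation treats missing as zero and needs matched tags", {
  g <- flat_grid()
  l1 <- layer("cattle", c(1, 2, rep(0, 30)), g)
  l2 <- layer("goats", c(3, 4, rep(0, 30)), g)
  expect_equal(sum_headcounts(list(l1, l2))$values[1:2], c(4, 6))
  expect_equal(sum_headcounts(list(l1))$values, l1$values)
  expect_error(sum_headcounts(list()), "no layers")

  set.seed(11)
  ls <- lapply(1:5, function(i) {
    v <- rpois(32, 10); v[sample(32, 4)] <- NA
    layer(paste0("sp", i), v, g)
  })
  oracle <- rowSums(vapply(ls, function(l) {
    v <- l$values; v[is.na(v)] <- 0; v
  }, numeric(32)))
  expect_equal(sum_headcounts(ls)$values, oracle)

  expect_error(sum_headcounts(list(layer("a", 1:32, g, decade = 1970L),
                                   layer("b", 1:32, g, decade = 1980L))),
               "mismatched temporal tags")
})

test_that("sd scaling clips at k, propagates NA, degenerates to zero", {
  g <- flat_grid()
  expect_equal(sd_scale(rep(5, 32)), rep(0, 32))
  set.seed(3)
  x <- rnorm(32, 10, 4); x[c(2, 17)] <- NA
  s <- sd_scale(x)
  expect_true(all(abs(s) <= 2.5, na.rm = TRUE))
  expect_true(all(is.na(s[c(2, 17)])))
  # direct z-then-clip oracle
  z <- (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
  expect_equal(s, pmin(2.5, pmax(-2.5, z)))
  # heavy-tailed input actually clips
  expect_equal(max(sd_scale(c(rep(0, 31), 100)), na.rm = TRUE), 2.5)
})

test_that("predictor sets resolve (name, year) to the right layer", {
  g <- flat_grid()
  mk <- function(nm, d) layer(nm, rnorm(32), g, decade = d)
  set.seed(8)
  pset <- predictor_set(c(
    list(layer("gens", rnorm(32), g)),
    lapply(c(1970L, 1980L, 1990L, 2000L), function(d) mk("pop", d))), g)
  pset <- add_change_layers(pset)

  expect_setequal(predictor_names(pset), c("gens", "pop", "pop_change"))
  # 1975 rounds up to the 1980 snapshot
  expect_identical(get_layer(pset, "pop", 1975L)$decade, 1980L)
  # 2004 clamps to 2000 and to the 1990-2000 change interval
  expect_identical(get_layer(pset, "pop", 2004L)$decade, 2000L)
  expect_identical(get_layer(pset, "pop_change", 2004L)$decade,
                   c(1990L, 2000L))
  # 1970 borrows the 1970-1980 interval
  expect_identical(get_layer(pset, "pop_change", 1970L)$decade,
                   c(1970L, 1980L))
  # static layers ignore the year
  expect_identical(get_layer(pset, "gens", 1971L),
                   get_layer(pset, "gens", 2008L))
  expect_error(get_layer(pset, "nope", 2000L), "unknown predictor")

  # change layers of a constant-in-time series are identically zero
  v <- rnorm(32)
  pc <- predictor_set(lapply(c(1970L, 1980L, 1990L, 2000L),
                             function(d) layer("u", v, g, decade = d)), g)
  pc <- add_change_layers(pc)
  for (y in c(1970L, 1985L, 2008L))
    expect_equal(get_layer(pc, "u_change", y)$values, rep(0, 32))
})

test_that("layer CSV round-trips losslessly", {
  g <- flat_grid()
  set.seed(6)
  ls <- list(layer("a", rnorm(32), g),
             layer("pop", exp(rnorm(32, 5)), g, decade = 2000L),
             layer("pop_change", rnorm(32), g, decade = c(1990L, 2000L)))
  ls[[1]]$values[4] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_layers_csv(ls, g, path)
  back <- read_layers_csv(path, g)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$values, ls[[i]]$values)
    expect_identical(back[[i]]$decade, ls[[i]]$decade)
  }
})
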