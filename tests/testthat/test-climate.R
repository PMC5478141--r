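g22 <- grid_spec(lat = c(0, 2), lon = c(0, 2))

test_that("grid validation rejects malformed coordinates", {
  expect_error(grid_spec(lat = c(2, 0), lon = c(0, 2)), "non-monotone")
  expect_error(grid_spec(lat = c(0, 1, 3), lon = c(0, 2)), "spacing")
  expect_error(grid_spec(lat = 0, lon = c(0, 2)), "2 x 2")
  expect_error(grid_spec(lat = c(0, 95), lon = c(0, 2)), "latitude")
})

test_that("Kelvin inputs are converted to Celsius", {
  f <- make_series(g22, 2000, 2000, fill = 300)
  expect_equal(f$values[1, 1, 1], 300 - 273.15)
  f2 <- make_series(g22, 2000, 2000, fill = 26.85)
  expect_equal(f2$values[1, 1, 1], 26.85)
})

test_that("identity regrid returns the field unchanged", {
  f <- make_series(g22, 2000, 2000,
                   fill = function(t, lat, lon) lat + lon + t)
  out <- regrid_to_common(f, g22)
  expect_identical(out$values, f$values)
})

test_that("regridding preserves a spatially constant field", {
  src <- grid_spec(lat = seq(-10, 10, 5), lon = seq(-10, 10, 5))
  f <- make_series(src, 2000, 2000, fill = 10)
  tgt <- grid_spec(lat = seq(-8, 8, 2), lon = seq(-8, 8, 2))
  out <- regrid_to_common(f, tgt)
  expect_true(all(out$values == 10))
})

test_that("bilinear interpolation matches hand arithmetic on a 2x2 corner field", {
  f <- make_series(g22, 2000, 2000, fill = 0)
  f$values[, 1, 1] <- 0; f$values[, 1, 2] <- 1
  f$values[, 2, 1] <- 1; f$values[, 2, 2] <- 2
  tgt <- grid_spec(lat = c(1, 1.5), lon = c(1, 1.5))
  out <- regrid_to_common(f, tgt)
  # hand bilinear: value = (1-wa)(1-wo)v00 + wa(1-wo)v10 + (1-wa)wo v01 + wa wo v11
  expect_equal(out$values[1, 1, 1], 1.0)            # midpoint of 0,1,1,2
  expect_equal(out$values[1, 1, 2], 0.25 * 0 + 0.75 * 1 + 0.5 * (1 - 0))
  expect_equal(out$values[1, 2, 2],
               0.25 * 0.25 * 0 + 0.75 * 0.25 * 1 + 0.25 * 0.75 * 1 +
                 0.75 * 0.75 * 2)
})

test_that("regrid falls back to nearest neighbor near missing cells and stays in range", {
  src <- grid_spec(lat = seq(0, 6, 2), lon = seq(0, 6, 2))
  set.seed(11)
  for (rep in 1:20) {
    f <- make_series(src, 2000, 2000,
                     fill = function(t, lat, lon) runif(length(lon), 0, 5))
    miss <- sample(16, 5)
    for (k in miss) f$values[, (k - 1) %% 4 + 1, (k - 1) %/% 4 + 1] <- NA
    tgt <- grid_spec(lat = seq(0.5, 5.5, 1), lon = seq(0.5, 5.5, 1))
    out <- regrid_to_common(f, tgt)
    lo <- min(f$values, na.rm = TRUE); hi <- max(f$values, na.rm = TRUE)
    expect_true(all(out$values >= lo - 1e-12 & out$values <= hi + 1e-12,
                    na.rm = TRUE))
  }
})

test_that("ensemble mean follows the valid-majority rule", {
  one <- make_series(g22, 2000, 2000, fill = 5)
  expect_equal(ensemble_mean(list(one))$values, one$values)

  a <- make_series(g22, 2000, 2000, fill = 1)
  b <- make_series(g22, 2000, 2000, fill = 3)
  expect_true(all(ensemble_mean(list(a, b))$values == 2))

  # 4 models, one missing at a cell: 3 of 4 >= half, mean of 1,2,3
  ms <- lapply(1:4, function(v) make_series(g22, 2000, 2000, fill = v))
  ms[[4]]$values[, 1, 1] <- NA
  em <- ensemble_mean(ms)
  expect_equal(em$values[1, 1, 1], 2)
  # 2 of 4 still valid (exactly half); 1 of 4 becomes missing
  ms[[3]]$values[, 1, 1] <- NA
  expect_equal(ensemble_mean(ms)$values[1, 1, 1], 1.5)
  ms[[2]]$values[, 1, 1] <- NA
  expect_true(is.na(ensemble_mean(ms)$values[1, 1, 1]))
})

test_that("ensemble mean is permutation-invariant and duplicate-idempotent", {
  set.seed(3)
  ms <- lapply(1:3, function(m)
    make_series(g22, 2000, 2001,
                fill = function(t, lat, lon) rnorm(length(lon), 10, 2)))
  e1 <- ensemble_mean(ms)
  e2 <- ensemble_mean(ms[c(3, 1, 2)])
  expect_equal(e1$values, e2$values)
  e3 <- ensemble_mean(c(ms, ms))
  expect_equal(e3$values, e1$values)
})

test_that("ensemble mean rejects misaligned inputs", {
  a <- make_series(g22, 2000, 2000, fill = 1)
  b <- make_series(grid_spec(lat = c(0, 3), lon = c(0, 3)), 2000, 2000,
                   fill = 1)
  expect_error(ensemble_mean(list(a, b)), "alignment")
  d <- make_series(g22, 2001, 2001, fill = 1)
  expect_error(ensemble_mean(list(a, d)), "alignment")
})

test_that("window mean averages monthly steps in the inclusive year range", {
  f <- make_series(g22, 2010, 2011, fill = 10)
  expect_true(all(window_mean(f, c(2010, 2011)) == 10))

  f2 <- make_series(g22, 2010, 2011,
                    fill = function(t, lat, lon)
                      rep(if (t <= 12) 10 else 12, length(lon)))
  expect_true(all(window_mean(f2, c(2010, 2011)) == 11))

  # linear monthly trend: mean of an arithmetic sequence
  f3 <- make_series(g22, 2016, 2050,
                    fill = function(t, lat, lon)
                      rep(10 + 0.01 * (t - 1), length(lon)))
  K <- 35 * 12
  expect_equal(window_mean(f3, c(2016, 2050))[1, 1],
               10 + 0.01 * (K - 1) / 2)
  expect_error(window_mean(f, c(1990, 1995)), "overlap")
})

test_that("anomaly subtracts the reference and propagates masks", {
  w <- matrix(12, 2, 2); r <- matrix(10, 2, 2)
  sc <- scenario_spec(8.5)
  an <- anomaly(w, r, g22, sc, n_models = 3)
  expect_true(all(an$values == 2))
  expect_true(all(anomaly(w, w, g22, sc)$values == 0))
  w2 <- w; w2[1, 1] <- NA
  expect_true(is.na(anomaly(w2, r, g22, sc)$values[1, 1]))
  r2 <- r; r2[2, 2] <- NA
  expect_true(is.na(anomaly(w, r2, g22, sc)$values[2, 2]))
  expect_error(anomaly(matrix(1, 3, 3), r, g22, sc), "alignment")
})

test_that("zero-noise synthetic anomaly equals trend times elapsed midpoint", {
  cfg <- synth_config(n_countries = 12L, res = 15, n_models = 2L,
                      noise_sd = 0, seed = 5L)
  hist <- gen_climate(cfg)
  mods <- gen_climate(cfg, 8.5, years = c(2016, 2050))
  sc <- scenario_spec(8.5, c(2016, 2050))
  an <- ensemble_anomaly(mods, hist, sc)
  g <- an$grid
  trend <- cfg$trend_per_decade[["8.5"]] / 10 *
    (1 + cfg$polar_amplification * abs(g$lat) / 90)
  elapsed <- (2016 + 2050) / 2 + 0.5 - 2016
  expected <- matrix(trend * elapsed, length(g$lat), length(g$lon))
  ok <- !is.na(an$values)
  expect_true(any(ok))
  expect_true(max(abs(an$values[ok] - expected[ok])) < 1e-6)
})

test_that("scenario specs pin the canonical windows and reject bad RCPs", {
  expect_error(scenario_spec(6.0), "rcp")
  sg <- scenario_grid()
  expect_length(sg, 6L)
  expect_equal(sg[["rcp8.5_2016-2050"]]$reference, c(1900L, 1950L))
})
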