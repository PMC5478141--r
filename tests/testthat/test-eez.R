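rect_ring <- function(x0, x1, y0, y1)
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))

test_that("merging by sovereignty partitions polygons by exact label", {
  p <- list(eez_polygon(1, "A", rect_ring(0, 1, 0, 1)),
            eez_polygon(2, "A", rect_ring(2, 3, 0, 1)),
            eez_polygon(3, "B", rect_ring(4, 5, 0, 1)))
  rg <- merge_by_sovereignty(p)
  expect_length(rg, 2L)
  expect_equal(rg[[1]]$country, "A")
  expect_length(rg[[1]]$polygons, 2L)
  expect_length(merge_by_sovereignty(p[1]), 1L)
  expect_length(merge_by_sovereignty(list()), 0L)
  # labels are exact keys: case matters
  q <- list(eez_polygon(1, "fiji", rect_ring(0, 1, 0, 1)),
            eez_polygon(2, "Fiji", rect_ring(0, 1, 0, 1)))
  expect_length(merge_by_sovereignty(q), 2L)
})

test_that("cells_in_region finds cell centers inside the polygon union", {
  g <- grid_spec(lat = c(0, 10, 20, 30), lon = c(0, 10, 20, 30))
  # rectangle containing exactly centers (lat 0, lon 0) and (lat 0, lon 10)
  rg <- merge_by_sovereignty(list(
    eez_polygon(1, "A", rect_ring(-4, 14, -4, 4))))[[1]]
  cells <- cells_in_region(rg, g)
  expect_equal(nrow(cells), 2L)
  expect_setequal(paste(cells[, "i"], cells[, "j"]), c("1 1", "1 2"))
  # polygon squeezed between centers contains none
  rg2 <- merge_by_sovereignty(list(
    eez_polygon(1, "B", rect_ring(2, 8, 2, 8))))[[1]]
  expect_equal(nrow(cells_in_region(rg2, g)), 0L)
  # boundary centers count as inside
  rg3 <- merge_by_sovereignty(list(
    eez_polygon(1, "C", rect_ring(0, 10, 0, 10))))[[1]]
  expect_equal(nrow(cells_in_region(rg3, g)), 4L)
})

test_that("antimeridian-crossing polygons are split and match brute force", {
  g <- grid_spec(lat = seq(-35, 35, 10), lon = seq(-175, 175, 10))
  # spans 170E -> -170E, lat -5..15: must cover centers at lon +-175,
  # lat 5 and 15 (the ring is written with a 20-degree eastward jump)
  ring <- rbind(c(170, -2), c(-170, -2), c(-170, 16), c(170, 16))
  rg <- merge_by_sovereignty(list(eez_polygon(1, "X", ring)))[[1]]
  cells <- cells_in_region(rg, g)
  expect_equal(nrow(cells), 4L)
  got <- apply(cells, 1, function(k) c(g$lat[k["i"]], g$lon[k["j"]]))
  # brute force: every grid center against the plain interval description
  want <- list()
  for (la in g$lat) for (lo in g$lon)
    if (la > -2 & la < 16 & (lo >= 170 | lo <= -170))
      want[[length(want) + 1L]] <- c(la, lo)
  expect_setequal(apply(got, 2, paste, collapse = ","),
                  vapply(want, paste, "", collapse = ","))
})

test_that("degenerate zero-area polygons yield an empty flagged set", {
  g <- grid_spec(lat = c(0, 10), lon = c(0, 10))
  rg <- merge_by_sovereignty(list(
    eez_polygon(1, "D", rbind(c(0, 0), c(5, 5), c(10, 10)))))[[1]]
  cells <- cells_in_region(rg, g)
  expect_equal(nrow(cells), 0L)
  expect_true(attr(cells, "degenerate"))
})

test_that("zonal mean averages contained cells and agrees with brute force", {
  g <- grid_spec(lat = c(0, 10, 20), lon = c(0, 10, 20))
  v <- matrix(NA_real_, 3, 3)
  v[1, 1] <- 1; v[1, 2] <- 2; v[2, 1] <- 3
  an <- make_anomaly(g, v)
  rg <- merge_by_sovereignty(list(
    eez_polygon(1, "A", rect_ring(-5, 15, -5, 15))))[[1]]
  z <- zonal_mean(an, rg)
  expect_equal(z$mean, 2.0)
  expect_equal(z$n_cells, 3L)
  expect_false(z$fallback)
  # single-cell region
  rg1 <- merge_by_sovereignty(list(
    eez_polygon(1, "B", rect_ring(-3, 3, -3, 3))))[[1]]
  an2 <- make_anomaly(g, matrix(0.7, 3, 3))
  expect_equal(zonal_mean(an2, rg1)$mean, 0.7)
})

test_that("zonal mean equals the all-cells scan oracle on random fixtures", {
  set.seed(21)
  g <- grid_spec(lat = seq(-35, 35, 10), lon = seq(-175, 175, 10))
  for (rep in 1:25) {
    v <- matrix(rnorm(length(g$lat) * length(g$lon)), length(g$lat))
    v[sample(length(v), 20)] <- NA
    an <- make_anomaly(g, v)
    x0 <- runif(1, -170, 100); x1 <- x0 + runif(1, 12, 60)
    y0 <- runif(1, -35, 10);   y1 <- y0 + runif(1, 12, 25)
    rg <- merge_by_sovereignty(list(
      eez_polygon(1, "R", rect_ring(x0, x1, y0, y1))))[[1]]
    oracle <- brute_zonal(an, function(lo) lo >= x0 & lo <= x1,
                          function(la) la >= y0 & la <= y1)
    z <- zonal_mean(an, rg)
    if (length(oracle)) {
      expect_equal(z$mean, mean(oracle))
      expect_equal(z$n_cells, length(oracle))
      expect_gte(z$mean, min(oracle))
      expect_lte(z$mean, max(oracle))
    } else {
      expect_true(z$fallback || z$excluded)
    }
  }
})

test_that("splitting a polygon into two abutting halves leaves the mean unchanged", {
  g <- grid_spec(lat = seq(-35, 35, 10), lon = seq(-175, 175, 10))
  set.seed(4)
  v <- matrix(rnorm(length(g$lat) * length(g$lon)), length(g$lat))
  an <- make_anomaly(g, v)
  whole <- merge_by_sovereignty(list(
    eez_polygon(1, "W", rect_ring(-32, 28, -22, 18))))[[1]]
  halves <- merge_by_sovereignty(list(
    eez_polygon(1, "W", rect_ring(-32, -2, -22, 18)),
    eez_polygon(2, "W", rect_ring(-2, 28, -22, 18))))[[1]]
  zw <- zonal_mean(an, whole); zh <- zonal_mean(an, halves)
  expect_equal(zh$mean, zw$mean)
  expect_equal(zh$n_cells, zw$n_cells)
})

test_that("tiny regions fall back to the nearest valid cell, or are excluded", {
  g <- grid_spec(lat = c(0, 10, 20), lon = c(0, 10, 20))
  v <- matrix(NA_real_, 3, 3)
  v[1, 1] <- 1.4
  an <- make_anomaly(g, v)
  # sliver between centers near (2.5, 2.5): nearest valid cell is (0, 0)
  rg <- merge_by_sovereignty(list(
    eez_polygon(1, "S", rect_ring(2, 3, 2, 3))))[[1]]
  z <- zonal_mean(an, rg)
  expect_true(z$fallback)
  expect_equal(z$mean, 1.4)
  expect_equal(z$n_cells, 1L)
  # no valid cell within 5 degrees: excluded
  v2 <- matrix(NA_real_, 3, 3); v2[3, 3] <- 1
  z2 <- zonal_mean(make_anomaly(g, v2), rg)
  expect_true(z2$excluded)
  expect_true(is.na(z2$mean))
})

test_that("package containment agrees with a winding-number oracle", {
  set.seed(9)
  for (rep in 1:15) {
    ring <- cbind(runif(3, -50, 50), runif(3, -40, 40))  # random triangle
    px <- runif(40, -60, 60); py <- runif(40, -50, 50)
    mine <- fishvuln:::point_in_ring(px, py, ring)
    theirs <- vapply(seq_along(px), function(k)
      winding_inside(px[k], py[k], ring), logical(1))
    expect_equal(mine, theirs)
  }
})
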