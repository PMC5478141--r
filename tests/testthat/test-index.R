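test_that("min-max normalization maps extremes to 0/1 and is affine-invariant", {
  expect_equal(minmax_normalize(c(1, 2, 3)), c(0, 0.5, 1))
  expect_warning(out <- minmax_normalize(c(5, 5, 5)), "constant")
  expect_equal(out, c(0.5, 0.5, 0.5))
  x <- c(0.3, 4, -2, 7, 1.1)
  expect_equal(minmax_normalize(2 * x + 7), minmax_normalize(x))
  expect_equal(minmax_normalize(c(1, NA, 3)), c(0, NA, 1))
  expect_error(minmax_normalize(c(1, NA, NA)), "at least 2")
  # idempotence: normalizing a normalized vector changes nothing
  expect_equal(minmax_normalize(minmax_normalize(x)), minmax_normalize(x))
})

test_that("exposure index is the normalized anomaly, shift-invariant", {
  expect_equal(exposure_index(c(0.5, 1.0, 1.5)), c(0, 0.5, 1))
  a <- c(0.2, 1.7, 0.9, 2.4)
  expect_equal(exposure_index(a + 0.3), exposure_index(a))
  expect_equal(which.max(exposure_index(a)), which.max(a))
})

test_that("sensitivity index renormalizes the equal-weight mean", {
  # all five variables share the same per-country pattern, so the
  # normalized means are (0, 1/3, 1) after renormalization of (.2,.4,.8)
  s <- as.data.frame(matrix(rep(c(0.2, 0.4, 0.8), 5), ncol = 5))
  expect_equal(sensitivity_index(s), c(0, 1/3, 1))
  # extremes: a country at the max (min) of every variable gets 1 (0)
  s2 <- data.frame(S1 = c(9, 1, 4), S2 = c(0.8, 0.1, 0.2),
                   S3 = c(0.05, 0.001, 0.01), S4 = c(1e6, 10, 1e3),
                   S5 = c(0.6, 0.02, 0.3))
  expect_equal(sensitivity_index(s2)[1], 1)
  expect_equal(sensitivity_index(s2)[2], 0)
})

test_that("adaptive capacity weights the fisheries pair at one half", {
  # rows B (all 0) and C (all 1) pin every normalization to identity
  ac <- rbind(A = c(1, 0, 0.5, 0.5, 0.5, 0.5),
              B = rep(0, 6), C = rep(1, 6))
  out <- adaptive_capacity_index(ac)
  expect_equal(unname(out), c(0.5 * (0.5 + 0.5), 0, 1))
  # partial derivatives of the aggregation: delta/4 for a fisheries
  # variable, delta/8 for a socio-economic one
  delta <- 0.08
  base <- rbind(A = rep(0.5, 6), B = rep(0, 6), C = rep(1, 6))
  f0 <- adaptive_capacity_index(base)[1]
  ac1 <- base; ac1["A", 1] <- 0.5 + delta
  expect_equal(unname(adaptive_capacity_index(ac1)[1] - f0), delta / 4)
  ac3 <- base; ac3["A", 3] <- 0.5 + delta
  expect_equal(unname(adaptive_capacity_index(ac3)[1] - f0), delta / 8)
})

test_that("vulnerability combines E + S - AC with ranks and quartiles", {
  vt <- vulnerability_index(c("hi", "mid", "lo"),
                            e_n = c(1, 0.5, 0), s_n = c(1, 0.5, 0),
                            a_n = c(0, 0.5, 1))
  expect_equal(vt$V_N, c(1, 0.5, 0))
  expect_equal(vt$country[vt$rank == 1], "hi")
  expect_equal(vt$country[vt$rank == 3], "lo")
  expect_error(vulnerability_index(c("a", "b"), 1, c(1, 2), c(1, 2)),
               "misalignment")
  expect_error(vulnerability_index(c("a", "a"), c(1, 2), c(1, 2), c(1, 2)),
               "duplicated")
})

test_that("147 countries split into quartiles 37/37/37/36 by rank blocks", {
  expect_equal(as.integer(table(rank_quartiles(1:147))), c(37L, 37L, 37L, 36L))
  expect_equal(rank_quartiles(c(1, 37, 38, 74, 75, 111, 112, 147), n = 147),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(as.integer(table(rank_quartiles(1:148))), rep(37L, 4))
  set.seed(2)
  vt <- vulnerability_index(sprintf("C%03d", 1:147), runif(147),
                            runif(147), runif(147))
  expect_setequal(vt$rank, 1:147)
  expect_equal(as.integer(table(vt$quartile)), c(37L, 37L, 37L, 36L))
  expect_true(all(diff(vt$V_N[order(vt$rank)]) <= 0))
})

test_that("ties in the score are broken alphabetically by country key", {
  vt <- vulnerability_index(c("b", "a", "c"), c(0.5, 0.5, 0),
                            c(0.5, 0.5, 1), c(0, 0, 1))
  expect_equal(vt$country[vt$rank == 1], "a")
  expect_equal(vt$country[vt$rank == 2], "b")
})

test_that("the full index matches an independent spreadsheet-style oracle", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    ind <- data.frame(country = sprintf("C%d", 1:n), E1 = runif(n, 0, 3))
    for (cn in paste0("S", 1:5)) ind[[cn]] <- runif(n, 0, 100)
    for (cn in paste0("AC", 1:6)) ind[[cn]] <- runif(n, -1, 50)
    got <- compute_index(ind)
    want <- brute_index(ind)
    m <- match(want$country, got$country)
    expect_equal(got$E_N[m], want$E_N, tolerance = 1e-12)
    expect_equal(got$S_N[m], want$S_N, tolerance = 1e-12)
    expect_equal(got$AC_N[m], want$AC_N, tolerance = 1e-12)
    expect_equal(got$V_N[m], want$V_N, tolerance = 1e-12)
    expect_equal(got$rank[m], want$rank)
  }
})

test_that("raising a sensitivity variable never makes a country less vulnerable", {
  set.seed(31)
  ind <- data.frame(country = sprintf("C%02d", 1:12), E1 = runif(12))
  for (cn in paste0("S", 1:5)) ind[[cn]] <- runif(12)
  for (cn in paste0("AC", 1:6)) ind[[cn]] <- runif(12)
  base_rank <- compute_index(ind)
  for (rep in 1:20) {
    k <- sample(12, 1); cn <- paste0("S", sample(5, 1))
    ind2 <- ind
    ind2[k, cn] <- ind2[k, cn] + runif(1, 0, 0.5)
    r2 <- compute_index(ind2)
    expect_lte(r2$rank[r2$country == ind$country[k]],
               base_rank$rank[base_rank$country == ind$country[k]])
  }
})

test_that("only exposure varies across scenarios", {
  set.seed(8)
  socio <- data.frame(country = sprintf("C%02d", 1:10))
  for (cn in paste0("S", 1:5)) socio[[cn]] <- runif(10)
  for (cn in paste0("AC", 1:6)) socio[[cn]] <- runif(10)
  e1 <- lapply(scenario_grid(), function(sc)
    data.frame(country = socio$country,
               anomaly_degC = runif(10, 0.5, 2) * sc$rcp))
  tabs <- run_scenarios(socio, e1)
  expect_length(tabs, 6L)
  for (t in tabs) {
    m <- match(socio$country, t$country)
    expect_equal(t$S_N[m], tabs[[1]]$S_N[match(socio$country,
                                               tabs[[1]]$country)])
    expect_equal(t$AC_N[m], tabs[[1]]$AC_N[match(socio$country,
                                                 tabs[[1]]$country)])
  }
  # identical anomalies across scenarios give identical tables
  e1_same <- lapply(scenario_grid(), function(sc)
    data.frame(country = socio$country, anomaly_degC = seq_len(10) / 10))
  tabs2 <- run_scenarios(socio, e1_same)
  for (t in tabs2[-1])
    expect_equal(t[, c("country", "V_N", "rank")],
                 tabs2[[1]][, c("country", "V_N", "rank")])
  # a missing scenario is skipped with a warning
  expect_warning(
    t3 <- run_scenarios(socio, c(e1[1], list(`rcp4.5_2016-2050` = NULL))),
    "skipped")
  expect_length(t3, 1L)
})
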