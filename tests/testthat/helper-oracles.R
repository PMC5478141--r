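# Fixture builders and independent oracles used across the suite.

# constant or function-valued monthly series on a grid
make_series <- function(grid, y0, y1, fill = 10, model = "m") {
  ax <- list(year = rep(y0:y1, each = 12L), month = rep(1:12, y1 - y0 + 1L))
  nt <- length(ax$year)
  arr <- array(NA_real_, c(nt, length(grid$lat), length(grid$lon)))
  if (is.function(fill)) {
    for (t in seq_len(nt))
      for (i in seq_along(grid$lat))
        arr[t, i, ] <- fill(t, grid$lat[i], grid$lon)
  } else arr[] <- fill
  gridded_series(grid, ax$year, ax$month, arr, model = model)
}

# anomaly field straight from a lat x lon matrix
make_anomaly <- function(grid, values, rcp = 8.5) {
  anomaly(values, matrix(0, length(grid$lat), length(grid$lon)),
          grid, scenario_spec(rcp), n_models = 1L)
}

# Winding-number point-in-polygon: an algorithm independent of the
# package's even-odd ray casting (agrees on simple polygons).
winding_inside <- function(px, py, ring, eps = 1e-9) {
  n <- nrow(ring)
  total <- 0
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    ax <- ring[k, 1] - px;  ay <- ring[k, 2] - py
    bx <- ring[k2, 1] - px; by <- ring[k2, 2] - py
    cross <- ax * by - ay * bx
    dot <- ax * bx + ay * by
    if (abs(cross) <= eps && dot <= eps) return(TRUE)  # on boundary
    total <- total + atan2(cross, dot)
  }
  abs(total) > pi
}

# Brute-force zonal mean: scan every grid cell, test containment of its
# center in any (antimeridian-aware) rectangle given as lon/lat bounds in
# plain interval form, average the valid anomaly values.
brute_zonal <- function(anom, lon_in, lat_in) {
  g <- anom$grid
  vals <- c()
  for (i in seq_along(g$lat)) for (j in seq_along(g$lon)) {
    if (lat_in(g$lat[i]) && lon_in(g$lon[j])) {
      v <- anom$values[i, j]
      if (is.finite(v)) vals <- c(vals, v)
    }
  }
  vals
}

# Spearman via explicit average ranks then the textbook Pearson formula.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Spreadsheet-style vulnerability index for a handful of countries:
# an independent step-by-step recomputation with explicit loops.
brute_index <- function(ind) {
  nrm <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi == lo) rep(0.5, length(v)) else (v - lo) / (hi - lo)
  }
  n <- nrow(ind)
  e_n <- nrm(ind$E1)
  s_cols <- sapply(paste0("S", 1:5), function(cn) nrm(ind[[cn]]))
  s_n <- nrm(apply(s_cols, 1, mean))
  a_cols <- sapply(paste0("AC", 1:6), function(cn) nrm(ind[[cn]]))
  a_raw <- numeric(n)
  for (k in seq_len(n))
    a_raw[k] <- 0.5 * (mean(a_cols[k, 1:2]) + mean(a_cols[k, 3:6]))
  a_n <- nrm(a_raw)
  v_raw <- e_n + s_n - a_n
  v_n <- nrm(v_raw)
  ord <- order(-v_n, ind$country)
  rank <- integer(n); rank[ord] <- seq_len(n)
  data.frame(country = ind$country, E_N = e_n, S_N = s_n, AC_N = a_n,
             V_N = v_n, rank = rank, stringsAsFactors = FALSE)
}

# a complete raw country record with sensible values, for overriding
complete_record <- function(country = "AAA", ...) {
  rec <- list(country = country, name = country, landlocked = FALSE,
              ldc = FALSE, oecd = FALSE, sids = FALSE, continent = "Africa",
              n_fishers = 1000, econ_active_pop = 1e5,
              fish_export_value = 5, total_export_value = 100,
              landings_2012 = 100, landings_2013 = 110, landings_2014 = 120,
              marine_fish_protein = 10, total_protein = 50,
              subsidy_pct_y1 = 10, subsidy_pct_y2 = 20, subsidy_pct_y3 = NA,
              industrial_catch = 90, smallscale_catch = 10,
              hale = 60, gov_voice = 0.1, gov_stability = -0.2,
              gov_effectiveness = 0.3, gov_regulatory = 0.2,
              gov_rule_of_law = 0, gov_corruption = -0.1,
              literacy_pct = 95, enrolment_pct = 80,
              gdp_per_capita = 5000, co2_per_capita = 2)
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

# small fast synthetic world for pipeline-level tests
tiny_config <- function(...) {
  defaults <- list(n_countries = 24L, res = 4, n_models = 3L,
                   noise_sd = 0.2, seed = 7L)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(synth_config, defaults)
}
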