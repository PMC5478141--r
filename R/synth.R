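#' Synthetic study configuration
#'
#' Frozen parameters for the synthetic analogue of the study inputs:
#' multi-model monthly SST grids with per-RCP warming trends, blocky EEZ
#' polygons tiling ocean bands, and country indicator tables drawn from
#' three socio-economic archetypes (LDC-like, OECD-like, middle). All
#' randomness derives from one root `seed` through fixed per-component
#' offsets (layout `seed + 200`, model biases `seed + 100`, monthly noise
#' `seed + 101 + experiment`, indicators `seed + 301`, missingness
#' `seed + 302`), so each component regenerates independently and
#' identically.
#'
#' @param n_countries Number of coastal countries (default 150).
#' @param mix Archetype fractions `c(ldc, oecd, middle)`, summing to 1.
#' @param res Grid cell size, degrees (default 2, global extent).
#' @param n_models Number of climate models in the ensemble (default 5).
#' @param trend_per_decade Named per-RCP linear SST trend, degC/decade
#'   (defaults 0.10 / 0.18 / 0.30 for RCP 2.6 / 4.5 / 8.5, ordered).
#' @param polar_amplification Fractional trend increase from equator to
#'   pole (trend is multiplied by `1 + polar_amplification * |lat| / 90`).
#' @param model_offset_sd Inter-model bias standard deviation, degC; each
#'   model's bias is shared between its historical and scenario runs.
#' @param noise_sd Monthly weather noise standard deviation, degC.
#' @param base_eq,base_polar Latitudinal base SST profile, degC:
#'   `base(lat) = base_polar + (base_eq - base_polar) cos^2(lat)`.
#' @param ice_lat Latitude poleward of which cells are masked (ice), deg.
#' @param split_frac Fraction of countries whose EEZ is stored as two
#'   abutting polygons sharing one sovereignty label.
#' @param sliver_frac Fraction of countries represented by a tiny
#'   "SIDS-like" sliver polygon that contains no grid-cell center.
#' @param missing_rate Fraction of middle-archetype countries given one
#'   missing indicator (to exercise the exclusion policy).
#' @param co2_intercept,co2_slope,co2_sd Log-linear coupling of per-capita
#'   CO2 emissions to GDP per capita:
#'   `log(co2) = co2_intercept + co2_slope * log(gdp) + N(0, co2_sd)`.
#' @param archetypes Named list of per-archetype distribution parameters;
#'   see `synth_archetypes()` for the defaults and their meaning.
#' @param seed Root integer seed (default 42).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_countries = 150L,
                         mix = c(ldc = 0.2, oecd = 0.2, middle = 0.6),
                         res = 2, n_models = 5L,
                         trend_per_decade = c("2.6" = 0.10, "4.5" = 0.18,
                                              "8.5" = 0.30),
                         polar_amplification = 0.6,
                         model_offset_sd = 0.3, noise_sd = 0.4,
                         base_eq = 28.5, base_polar = -1.5,
                         ice_lat = 66,
                         split_frac = 0.10, sliver_frac = 0.03,
                         missing_rate = 0.05,
                         co2_intercept = -7.8, co2_slope = 0.85,
                         co2_sd = 0.5,
                         archetypes = synth_archetypes(),
                         seed = 42L) {
  if (abs(sum(mix) - 1) > 1e-9) stop("archetype fractions must sum to 1",
                                     call. = FALSE)
  if (is.unsorted(trend_per_decade))
    stop("warming trends must be ordered RCP 2.6 <= 4.5 <= 8.5",
         call. = FALSE)
  if (model_offset_sd < 0 || noise_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "synth_config")
}

#' Default archetype distribution parameters
#'
#' LDC-like countries draw low GDP, governance, healthy life expectancy
#' and education, high fish-protein and fisher shares, and low subsidies
#' and industrial catch shares; OECD-like countries the opposite; the
#' middle archetype sits between with wider spread. Shares are
#' beta-distributed (given mean and concentration), monetary quantities
#' log-normal, scores normal.
#'
#' @return Named list (`ldc`, `oecd`, `middle`) of parameter lists.
#' @export
synth_archetypes <- function() {
  list(
    ldc = list(gdp_meanlog = log(900), gdp_sdlog = 0.5,
               gov_mean = -1.2, hale_mean = 50,
               protein_share_mean = 0.35, fisher_share_mean = 0.030,
               subsidy_mean = 2.5, industrial_share_mean = 0.12,
               export_share_mean = 0.12, literacy_mean = 50),
    oecd = list(gdp_meanlog = log(42000), gdp_sdlog = 0.35,
                gov_mean = 1.6, hale_mean = 74,
                protein_share_mean = 0.06, fisher_share_mean = 0.002,
                subsidy_mean = 13, industrial_share_mean = 0.88,
                export_share_mean = 0.01, literacy_mean = 99),
    middle = list(gdp_meanlog = log(8000), gdp_sdlog = 0.7,
                  gov_mean = 0, hale_mean = 63,
                  protein_share_mean = 0.15, fisher_share_mean = 0.010,
                  subsidy_mean = 7, industrial_share_mean = 0.50,
                  export_share_mean = 0.04, literacy_mean = 85))
}

# Band geometry shared by the land mask and the EEZ tiling: six 12-degree
# ocean bands separated by 4-degree land strips, spanning [-46, 46].
.synth_bands <- function() {
  bottoms <- -46 + (0:5) * 16
  list(bottoms = bottoms, tops = bottoms + 12, n = 6L)
}

#' Land/ice mask of the synthetic world
#'
#' @param cfg A [synth_config()].
#' @param grid Optional [grid_spec()]; default the config's global grid.
#' @return Logical `lat x lon` matrix, `TRUE` where masked (land or ice).
#' @export
synth_land_mask <- function(cfg, grid = global_grid(cfg$res)) {
  b <- .synth_bands()
  lat <- grid$lat
  in_band <- rep(FALSE, length(lat))
  for (k in seq_len(b$n))
    in_band <- in_band | (lat >= b$bottoms[k] & lat <= b$tops[k])
  land_lat <- (abs(lat) > cfg$ice_lat) |
    (lat >= min(b$bottoms) & lat <= max(b$tops) & !in_band)
  matrix(land_lat, length(lat), length(grid$lon))
}

# Deterministic country layout: archetypes, lattice slots, split/sliver
# designations and continent labels. Seeded at seed + 200.
synth_layout <- function(cfg) {
  n <- cfg$n_countries
  b <- .synth_bands()
  ncols <- ceiling(n / b$n)
  set.seed(cfg$seed + 200L)
  counts <- c(ldc = round(n * cfg$mix[["ldc"]]),
              oecd = round(n * cfg$mix[["oecd"]]))
  counts <- c(counts, middle = n - sum(counts))
  archetype <- sample(rep(names(counts), counts))
  slot <- sample(b$n * ncols)[seq_len(n)]
  n_split <- round(cfg$split_frac * n)
  n_sliver <- max(2L, round(cfg$sliver_frac * n))
  split <- rep(FALSE, n)
  split[sample(n, n_split)] <- TRUE
  sliver <- rep(FALSE, n)
  eligible <- which(archetype != "oecd" & !split)
  sliver[sample(eligible, min(n_sliver, length(eligible)))] <- TRUE
  col <- (slot - 1L) %/% b$n + 1L
  continents <- c("Africa", "Asia", "Europe",
                  "North America and the Caribbean", "Oceania",
                  "South America")
  data.frame(country = sprintf("C%03d", seq_len(n)),
             archetype = archetype,
             slot_row = (slot - 1L) %% b$n + 1L,
             slot_col = col,
             split = split, sliver = sliver,
             continent = continents[(col - 1L) %% 6L + 1L],
             stringsAsFactors = FALSE)
}

#' Generate synthetic EEZ polygons
#'
#' Tiles the ocean bands with rectangular EEZs, one lattice slot per
#' country. About 10% of countries are written as two abutting polygons
#' sharing one sovereignty label (to exercise merging) and a few countries
#' are tiny slivers placed between grid-cell centers (to exercise the
#' nearest-cell fallback).
#'
#' @param cfg A [synth_config()].
#' @return List of [eez_polygon()].
#' @export
gen_eezs <- function(cfg) {
  lay <- synth_layout(cfg)
  b <- .synth_bands()
  ncols <- ceiling(cfg$n_countries / b$n)
  lon_edges <- seq(-180, 180, length.out = ncols + 1L)
  grid <- global_grid(cfg$res)
  inset <- 0.3
  polys <- list()
  rect <- function(x0, x1, y0, y1)
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  for (k in seq_len(nrow(lay))) {
    r <- lay$slot_row[k]; cc <- lay$slot_col[k]
    x0 <- lon_edges[cc] + inset; x1 <- lon_edges[cc + 1L] - inset
    y0 <- b$bottoms[r] + inset;  y1 <- b$tops[r] - inset
    key <- lay$country[k]
    if (lay$sliver[k]) {
      # a box centered on a cell corner, too small to contain any center
      corner_lon <- grid$lon[which.min(abs(grid$lon - (x0 + x1) / 2))] +
        cfg$res / 2
      corner_lat <- grid$lat[which.min(abs(grid$lat - (y0 + y1) / 2))] +
        cfg$res / 2
      h <- cfg$res / 8
      polys[[length(polys) + 1L]] <- eez_polygon(
        paste0(key, "-sliver"), key,
        rect(corner_lon - h, corner_lon + h, corner_lat - h,
             corner_lat + h))
    } else if (lay$split[k]) {
      xm <- (x0 + x1) / 2
      polys[[length(polys) + 1L]] <-
        eez_polygon(paste0(key, "-a"), key, rect(x0, xm, y0, y1))
      polys[[length(polys) + 1L]] <-
        eez_polygon(paste0(key, "-b"), key, rect(xm, x1, y0, y1))
    } else {
      polys[[length(polys) + 1L]] <-
        eez_polygon(key, key, rect(x0, x1, y0, y1))
    }
  }
  polys
}

# base SST latitudinal profile, degC
.synth_base <- function(cfg, lat)
  cfg$base_polar + (cfg$base_eq - cfg$base_polar) * cos(lat * pi / 180)^2

# per-model bias offsets, shared across experiments (seed + 100)
.synth_offsets <- function(cfg) {
  set.seed(cfg$seed + 100L)
  stats::rnorm(cfg$n_models, 0, cfg$model_offset_sd)
}

.synth_series <- function(cfg, years, trend_degC_yr, noise_seed) {
  grid <- global_grid(cfg$res)
  ax <- monthly_axis(years[1], years[2])
  nt <- length(ax$year)
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  base_l <- .synth_base(cfg, grid$lat)
  tfrac <- ax$year + (ax$month - 0.5) / 12 - 2016
  mask <- synth_land_mask(cfg, grid)
  mask_rep <- rep(as.vector(mask), each = nt)
  offs <- .synth_offsets(cfg)
  set.seed(noise_seed)
  out <- vector("list", cfg$n_models)
  for (m in seq_len(cfg$n_models)) {
    arr <- if (cfg$noise_sd > 0)
      array(stats::rnorm(nt * nlat * nlon, 0, cfg$noise_sd),
            dim = c(nt, nlat, nlon))
    else array(0, dim = c(nt, nlat, nlon))
    arr <- arr + rep(base_l, each = nt) + offs[m]
    if (any(trend_degC_yr != 0))
      arr <- arr + as.vector(outer(tfrac, trend_degC_yr))
    arr[mask_rep] <- NA_real_
    out[[m]] <- gridded_series(grid, ax$year, ax$month, arr,
                               model = sprintf("model%02d", m))
  }
  out
}

#' Generate synthetic multi-model SST series
#'
#' Scenario runs follow `SST(t, lat, lon) = base(lat) + trend(lat) * (t -
#' 2016) + model bias + noise` with the per-RCP trend amplified toward the
#' poles; the historical run has no trend. Model biases are shared between
#' a model's historical and scenario runs, as for a real model's
#' climatological bias, so they cancel in anomalies.
#'
#' @param cfg A [synth_config()].
#' @param rcp One of 2.6, 4.5, 8.5, or `NULL` for the historical run.
#' @param years Inclusive year range; defaults to 2016--2100 for scenario
#'   runs and 1900--1950 for the historical run.
#' @return List of per-model [gridded_series()].
#' @export
gen_climate <- function(cfg, rcp = NULL,
                        years = if (is.null(rcp)) c(1900, 1950)
                                else c(2016, 2100)) {
  grid <- global_grid(cfg$res)
  if (is.null(rcp)) {
    return(.synth_series(cfg, years, rep(0, length(grid$lat)),
                         noise_seed = cfg$seed + 101L))
  }
  key <- sprintf("%.1f", as.numeric(rcp))
  if (!key %in% names(cfg$trend_per_decade))
    stop("unknown rcp: ", rcp, call. = FALSE)
  trend <- cfg$trend_per_decade[[key]] / 10 *
    (1 + cfg$polar_amplification * abs(grid$lat) / 90)
  .synth_series(cfg, years, trend,
                noise_seed = cfg$seed + 101L +
                  match(key, names(cfg$trend_per_decade)))
}

.rbeta_mc <- function(n, mean, conc)
  stats::rbeta(n, mean * conc, (1 - mean) * conc)

#' Generate the synthetic country table
#'
#' Draws every raw socio-economic variable per country from its archetype
#' distribution ([synth_archetypes()]), couples per-capita CO2 emissions
#' to GDP log-linearly, and injects one missing value into a small
#' fraction of middle-archetype countries. Deterministic for a given
#' config.
#'
#' @param cfg A [synth_config()].
#' @return List: `records` (raw country table, see
#'   [read_country_table()]), `labels` (data.frame `country`,
#'   `archetype`).
#' @export
gen_indicators <- function(cfg) {
  lay <- synth_layout(cfg)
  n <- nrow(lay)
  p <- cfg$archetypes
  pull <- function(field) vapply(lay$archetype,
                                 function(a) p[[a]][[field]], numeric(1))
  set.seed(cfg$seed + 301L)
  gdp <- stats::rlnorm(n, pull("gdp_meanlog"), pull("gdp_sdlog"))
  gov_mean <- stats::rnorm(n, pull("gov_mean"), 0.3)
  gov <- sapply(1:6, function(d) pmin(pmax(
    stats::rnorm(n, gov_mean, 0.25), -2.5), 2.5))
  hale <- stats::rnorm(n, pull("hale_mean"), 2)
  protein_share <- .rbeta_mc(n, pull("protein_share_mean"), 20)
  fisher_share <- .rbeta_mc(n, pull("fisher_share_mean"), 50)
  subsidy <- sapply(1:3, function(y) pmax(
    stats::rnorm(n, pull("subsidy_mean"), 1.2), 0))
  ishare <- .rbeta_mc(n, pull("industrial_share_mean"), 20)
  eshare <- .rbeta_mc(n, pull("export_share_mean"), 30)
  literacy <- pmin(pmax(stats::rnorm(n, pull("literacy_mean"), 5), 5), 100)
  enrol <- pmin(pmax(literacy + stats::rnorm(n, 0, 2), 5), 100)
  pop <- stats::rlnorm(n, log(3e6), 1)
  total_protein <- pmin(pmax(stats::rnorm(n, 75, 10), 40), 120)
  catch <- stats::rlnorm(n, log(2e5), 1.2)
  land <- sapply(1:3, function(y) catch * stats::rlnorm(n, 0, 0.15))
  total_export <- stats::rlnorm(n, log(5e9), 1.5)
  co2 <- exp(cfg$co2_intercept + cfg$co2_slope * log(gdp) +
               stats::rnorm(n, 0, cfg$co2_sd))
  rec <- data.frame(
    country = lay$country, name = paste("Country", lay$country),
    landlocked = FALSE,
    ldc = lay$archetype == "ldc", oecd = lay$archetype == "oecd",
    sids = lay$sliver, continent = lay$continent,
    n_fishers = round(fisher_share * pop),
    econ_active_pop = round(pop),
    fish_export_value = eshare * total_export,
    total_export_value = total_export,
    landings_2012 = land[, 1], landings_2013 = land[, 2],
    landings_2014 = land[, 3],
    marine_fish_protein = protein_share * total_protein,
    total_protein = total_protein,
    subsidy_pct_y1 = subsidy[, 1], subsidy_pct_y2 = subsidy[, 2],
    subsidy_pct_y3 = subsidy[, 3],
    industrial_catch = ishare * catch,
    smallscale_catch = (1 - ishare) * catch,
    hale = hale,
    gov_voice = gov[, 1], gov_stability = gov[, 2],
    gov_effectiveness = gov[, 3], gov_regulatory = gov[, 4],
    gov_rule_of_law = gov[, 5], gov_corruption = gov[, 6],
    literacy_pct = literacy, enrolment_pct = enrol,
    gdp_per_capita = gdp, co2_per_capita = co2,
    stringsAsFactors = FALSE)
  # inject missingness into middle-archetype countries only, so archetype
  # recovery statistics are not diluted
  set.seed(cfg$seed + 302L)
  mid <- which(lay$archetype == "middle")
  n_miss <- round(cfg$missing_rate * length(mid))
  if (n_miss > 0) {
    victims <- sample(mid, n_miss)
    fields <- list(
      c("total_protein", "marine_fish_protein"),
      c("hale"),
      c("literacy_pct", "enrolment_pct"),
      c("gov_voice", "gov_stability", "gov_effectiveness"),
      c("subsidy_pct_y1", "subsidy_pct_y2", "subsidy_pct_y3"))
    for (i in seq_along(victims))
      rec[victims[i], fields[[(i - 1L) %% length(fields) + 1L]]] <- NA
  }
  list(records = rec,
       labels = data.frame(country = lay$country,
                           archetype = lay$archetype,
                           stringsAsFactors = FALSE))
}
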