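#' Rectilinear grid specification
#'
#' Defines the regular latitude/longitude grid on which gridded sea surface
#' temperature (SST) fields live. Cell centers must be equally spaced and
#' ascending; longitudes are expressed in degrees east in `[-180, 180)`.
#'
#' @param lat Numeric vector of latitude cell centers, degrees north,
#'   strictly ascending, within `[-90, 90]`.
#' @param lon Numeric vector of longitude cell centers, degrees east,
#'   strictly ascending, within `[-180, 180)`.
#' @return An object of class `grid_spec` with elements `lat`, `lon`,
#'   `dlat`, `dlon` (cell spacings in degrees).
#' @examples
#' g <- grid_spec(lat = seq(-89, 89, by = 2), lon = seq(-179, 179, by = 2))
#' @export
grid_spec <- function(lat, lon) {
  lat <- as.numeric(lat)
  lon <- as.numeric(lon)
  if (length(lat) < 2L || length(lon) < 2L)
    stop("invalid grid: need at least 2 x 2 cells", call. = FALSE)
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("invalid grid: non-finite coordinates", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("invalid grid: latitude outside [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon >= 180))
    stop("invalid grid: longitude outside [-180, 180)", call. = FALSE)
  .check_regular <- function(x, what) {
    d <- diff(x)
    if (any(d <= 0))
      stop("invalid grid: non-monotone ", what, " coordinates", call. = FALSE)
    if (diff(range(d)) > 1e-6 * mean(d))
      stop("invalid grid: non-constant ", what, " spacing", call. = FALSE)
    mean(d)
  }
  structure(
    list(lat = lat, lon = lon,
         dlat = .check_regular(lat, "latitude"),
         dlon = .check_regular(lon, "longitude")),
    class = "grid_spec")
}

#' Global grid at a given resolution
#'
#' @param res Cell size in degrees (cells centered at `-90 + res/2`, ...).
#' @return A [grid_spec()].
#' @export
global_grid <- function(res = 1) {
  grid_spec(lat = seq(-90 + res / 2, 90 - res / 2, by = res),
            lon = seq(-180 + res / 2, 180 - res / 2, by = res))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, %.3g deg lat x %.3g deg lon\n",
              length(x$lat), length(x$lon), x$dlat, x$dlon))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    max(abs(a$lat - b$lat)) <= tol && max(abs(a$lon - b$lon)) <= tol
}

#' Monthly SST series on a grid
#'
#' A (time x lat x lon) array of monthly sea surface temperatures for one
#' climate model and one experiment. Values in Kelvin are detected (median of
#' non-missing values above 200) and converted to degrees Celsius, matching
#' the common convention for the CMIP "tos" variable. Missing cells (land,
#' ice) are `NA`.
#'
#' @param grid A [grid_spec()].
#' @param year,month Integer vectors (equal length) giving the time axis.
#' @param values Array with dim `c(length(year), length(grid$lat),
#'   length(grid$lon))`, degrees C or K.
#' @param model Optional model label.
#' @return An object of class `gridded_series`.
#' @export
gridded_series <- function(grid, year, month, values, model = NA_character_) {
  stopifnot(inherits(grid, "grid_spec"))
  year <- as.integer(year); month <- as.integer(month)
  if (length(year) != length(month))
    stop("year and month must have equal length", call. = FALSE)
  if (any(month < 1L | month > 12L))
    stop("month outside 1..12", call. = FALSE)
  dv <- dim(values)
  if (is.null(dv) || length(dv) != 3L ||
      !all(dv == c(length(year), length(grid$lat), length(grid$lon))))
    stop("values must be a (time x lat x lon) array matching grid and times",
         call. = FALSE)
  med <- stats::median(values, na.rm = TRUE)
  if (is.finite(med) && med > 200) values <- values - 273.15
  rng <- range(values, na.rm = TRUE, finite = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -5 || rng[2] > 60))
    warning("SST values outside [-5, 60] degC after unit conversion",
            call. = FALSE)
  structure(list(grid = grid, year = year, month = month, values = values,
                 model = model),
            class = "gridded_series")
}

#' @export
print.gridded_series <- function(x, ...) {
  cat(sprintf("gridded_series: %s, %d monthly steps (%d-%02d .. %d-%02d), %d x %d cells\n",
              if (is.na(x$model)) "<unnamed model>" else x$model,
              length(x$year), x$year[1], x$month[1],
              x$year[length(x$year)], x$month[length(x$month)],
              length(x$grid$lat), length(x$grid$lon)))
  invisible(x)
}

monthly_axis <- function(y0, y1) {
  yrs <- y0:y1
  list(year = rep(yrs, each = 12L), month = rep(1:12, length(yrs)))
}

#' Scenario specification
#'
#' Pins down one of the six study scenarios: a representative concentration
#' pathway (RCP 2.6, 4.5 or 8.5) combined with a 35-year projection window
#' (near future 2016--2050 or distant future 2066--2100), anomalies taken
#' against the 1900--1950 reference climatology.
#'
#' @param rcp One of 2.6, 4.5, 8.5.
#' @param window Length-2 inclusive year range; defaults to the near-future
#'   window `c(2016, 2050)`.
#' @param reference Length-2 inclusive reference year range, default
#'   `c(1900, 1950)`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(rcp, window = c(2016, 2050),
                          reference = c(1900, 1950)) {
  rcp <- as.numeric(rcp)
  if (!rcp %in% c(2.6, 4.5, 8.5))
    stop("rcp must be one of 2.6, 4.5, 8.5", call. = FALSE)
  window <- as.integer(window); reference <- as.integer(reference)
  if (length(window) != 2L || window[2] < window[1])
    stop("window must be an increasing year range", call. = FALSE)
  if (length(reference) != 2L || reference[2] < reference[1])
    stop("reference must be an increasing year range", call. = FALSE)
  structure(list(rcp = rcp, window = window, reference = reference),
            class = "scenario_spec")
}

#' The six canonical study scenarios
#'
#' Three RCPs crossed with the two 35-year projection windows.
#' @return List of six [scenario_spec()] objects, named e.g. `"rcp8.5_2016-2050"`.
#' @export
scenario_grid <- function() {
  out <- list()
  for (w in list(c(2016L, 2050L), c(2066L, 2100L)))
    for (r in c(2.6, 4.5, 8.5))
      out[[sprintf("rcp%.1f_%d-%d", r, w[1], w[2])]] <- scenario_spec(r, w)
  out
}

scenario_label <- function(sc)
  sprintf("rcp%.1f_%d-%d", sc$rcp, sc$window[1], sc$window[2])

#' Regrid a monthly series onto a common grid
#'
#' Bilinear interpolation from the source grid onto the cell centers of
#' `target`. Where some of the four surrounding source cells are missing,
#' the rules are: three or four valid neighbors, weight-renormalized
#' bilinear mean of the valid ones; one or two valid, nearest (largest
#' weight) valid neighbor; none valid, missing. Longitude wraps when the
#' source grid spans the full circle; otherwise targets must fall within
#' half a source cell of the source extent.
#'
#' @param field A [gridded_series()].
#' @param target A [grid_spec()].
#' @return A [gridded_series()] on `target`, same time axis.
#' @export
regrid_to_common <- function(field, target) {
  stopifnot(inherits(field, "gridded_series"), inherits(target, "grid_spec"))
  src <- field$grid
  if (grids_equal(src, target)) {
    field$grid <- target
    return(field)
  }
  nlat_s <- length(src$lat); nlon_s <- length(src$lon)
  wrap <- nlon_s * src$dlon >= 360 - 1e-6

  brak <- function(x, centers, d, circular) {
    # returns i0, i1, w1 (weight of i1); clamps at edges within half a cell
    n <- length(centers)
    if (circular) {
      # position in units of cells from centers[1], modulo n
      u <- (x - centers[1]) / d
      u <- u %% n
      i0 <- floor(u) + 1L
      w1 <- u - floor(u)
      i1 <- ifelse(i0 == n, 1L, i0 + 1L)
      list(i0 = as.integer(i0), i1 = as.integer(i1), w1 = w1)
    } else {
      if (any(x < centers[1] - d / 2 - 1e-9) ||
          any(x > centers[n] + d / 2 + 1e-9))
        stop("source grid does not cover target domain", call. = FALSE)
      u <- (x - centers[1]) / d
      u <- pmin(pmax(u, 0), n - 1)
      i0 <- pmin(floor(u) + 1L, n - 1L)
      w1 <- u - (i0 - 1L)
      list(i0 = as.integer(i0), i1 = as.integer(i0 + 1L), w1 = w1)
    }
  }

  bl <- brak(target$lat, src$lat, src$dlat, circular = FALSE)
  bo <- brak(target$lon, src$lon, src$dlon, circular = wrap)

  nlatT <- length(target$lat); nlonT <- length(target$lon)
  # corner indexing: all (target lat, target lon) pairs, lat varying fastest
  I0 <- rep(bl$i0, nlonT); I1 <- rep(bl$i1, nlonT)
  WA <- rep(bl$w1, nlonT)
  J0 <- rep(bo$i0, each = nlatT); J1 <- rep(bo$i1, each = nlatT)
  WO <- rep(bo$w1, each = nlatT)
  lin <- function(i, j) i + (j - 1L) * nlat_s
  IDX <- cbind(lin(I0, J0), lin(I1, J0), lin(I0, J1), lin(I1, J1))
  W <- cbind((1 - WA) * (1 - WO), WA * (1 - WO), (1 - WA) * WO, WA * WO)

  nt <- length(field$year)
  V <- matrix(field$values, nrow = nt)   # nt x (nlat_s * nlon_s)
  ncT <- nlatT * nlonT
  out <- matrix(NA_real_, nt, ncT)
  for (t in seq_len(nt)) {
    v4 <- matrix(V[t, IDX], ncol = 4L)
    ok <- !is.na(v4)
    nv <- rowSums(ok)
    wv <- W * ok
    sw <- rowSums(wv)
    est <- rowSums(wv * ifelse(ok, v4, 0)) / sw
    # 1-2 valid neighbors: take the valid corner with the largest weight
    few <- which(nv > 0L & nv < 3L)
    if (length(few)) {
      for (k in few) {
        cand <- which(ok[k, ])
        est[k] <- v4[k, cand[which.max(W[k, cand])]]
      }
    }
    est[nv == 0L] <- NA_real_
    out[t, ] <- est
  }
  gridded_series(target, field$year, field$month,
                 array(out, dim = c(nt, nlatT, nlonT)), model = field$model)
}

#' Multi-model ensemble mean
#'
#' Cellwise unweighted mean over models at each time step. A cell is missing
#' when fewer than half of the models have valid data there.
#'
#' @param fields List of [gridded_series()] on one grid and time axis.
#' @return A [gridded_series()] (model label `"ensemble"`).
#' @export
ensemble_mean <- function(fields) {
  if (!length(fields)) stop("need at least one model field", call. = FALSE)
  stopifnot(all(vapply(fields, inherits, logical(1), "gridded_series")))
  ref <- fields[[1]]
  for (f in fields[-1]) {
    if (!grids_equal(f$grid, ref$grid))
      stop("alignment error: model grids differ", call. = FALSE)
    if (length(f$year) != length(ref$year) ||
        any(f$year != ref$year) || any(f$month != ref$month))
      stop("alignment error: model time axes differ", call. = FALSE)
  }
  n <- length(fields)
  s <- array(0, dim = dim(ref$values))
  cnt <- array(0L, dim = dim(ref$values))
  for (f in fields) {
    ok <- !is.na(f$values)
    s[ok] <- s[ok] + f$values[ok]
    cnt <- cnt + ok
  }
  m <- s / cnt
  m[2L * cnt < n] <- NA_real_
  gridded_series(ref$grid, ref$year, ref$month, m, model = "ensemble")
}

#' Time-window mean map
#'
#' Unweighted mean over every monthly step whose year falls in the inclusive
#' range, cell by cell (missing steps at a cell are ignored; all-missing
#' cells stay missing).
#'
#' @param field A [gridded_series()].
#' @param years Length-2 inclusive year range.
#' @return A `lat x lon` matrix, degrees C.
#' @export
window_mean <- function(field, years) {
  stopifnot(inherits(field, "gridded_series"))
  years <- as.integer(years)
  sel <- field$year >= years[1] & field$year <= years[2]
  if (!any(sel))
    stop("window does not overlap the series time axis", call. = FALSE)
  v <- field$values[sel, , , drop = FALSE]
  out <- apply(v, c(2L, 3L), function(z) {
    z <- z[!is.na(z)]
    if (length(z)) mean(z) else NA_real_
  })
  out
}

#' SST anomaly field
#'
#' Cellwise difference between a projection-window mean map and the
#' reference-climatology map; missing wherever either input is missing.
#'
#' @param window_map,reference_map `lat x lon` matrices on `grid`, degrees C.
#' @param grid The shared [grid_spec()].
#' @param scenario The [scenario_spec()] the window map belongs to.
#' @param n_models Number of models behind the ensemble.
#' @return An object of class `anomaly_field`: `grid`, `values`
#'   (`lat x lon`, delta degrees C), `scenario`, `n_models`.
#' @export
anomaly <- function(window_map, reference_map, grid, scenario,
                    n_models = NA_integer_) {
  stopifnot(inherits(grid, "grid_spec"))
  dref <- c(length(grid$lat), length(grid$lon))
  if (!all(dim(window_map) == dref) || !all(dim(reference_map) == dref))
    stop("alignment error: maps do not match the grid", call. = FALSE)
  structure(list(grid = grid, values = window_map - reference_map,
                 scenario = scenario, n_models = as.integer(n_models)),
            class = "anomaly_field")
}

#' @export
print.anomaly_field <- function(x, ...) {
  cat(sprintf("anomaly_field: %s, %d x %d cells, %d models, range [%.3f, %.3f] degC\n",
              scenario_label(x$scenario), length(x$grid$lat),
              length(x$grid$lon), x$n_models,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Ensemble anomaly for one scenario
#'
#' Convenience wrapper chaining the exposure steps: regrid every model onto
#' the common grid, take the ensemble mean of the scenario and historical
#' runs, average each over its window, and subtract.
#'
#' @param scenario_fields,historical_fields Lists of per-model
#'   [gridded_series()] (scenario run and historical run).
#' @param scenario A [scenario_spec()].
#' @param target Common [grid_spec()]; default the grid of the first field.
#' @return An [anomaly()] field.
#' @export
ensemble_anomaly <- function(scenario_fields, historical_fields, scenario,
                             target = scenario_fields[[1]]$grid) {
  sc <- lapply(scenario_fields, regrid_to_common, target = target)
  hi <- lapply(historical_fields, regrid_to_common, target = target)
  wm <- window_mean(ensemble_mean(sc), scenario$window)
  rm_ <- window_mean(ensemble_mean(hi), scenario$reference)
  anomaly(wm, rm_, target, scenario, n_models = length(sc))
}
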