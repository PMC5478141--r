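#' EEZ polygon
#'
#' One polygon feature of an exclusive economic zone, carrying the
#' sovereignty label used for merging. Rings are stored as open vertex
#' lists (the closing edge back to the first vertex is implicit);
#' longitudes are normalized to `[-180, 180)`.
#'
#' @param id Feature identifier.
#' @param sovereignty Non-empty country key; labels are exact (case-sensitive).
#' @param rings A single two-column (lon, lat) matrix, or a list of them
#'   (first ring outer boundary, later rings holes under the even-odd rule).
#' @return Object of class `eez_polygon`.
#' @export
eez_polygon <- function(id, sovereignty, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    storage.mode(r) <- "double"
    if (ncol(r) != 2L) stop("ring must be a 2-column (lon, lat) matrix",
                            call. = FALSE)
    # drop explicit closure, normalize longitudes
    if (nrow(r) > 1L && all(r[1L, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3L) stop("ring needs at least 3 vertices", call. = FALSE)
    r[, 1L] <- ((r[, 1L] + 180) %% 360) - 180
    r
  })
  if (!is.character(sovereignty) || !nzchar(sovereignty))
    stop("sovereignty label must be a non-empty string", call. = FALSE)
  structure(list(id = id, sovereignty = sovereignty, rings = rings),
            class = "eez_polygon")
}

#' Merge EEZ polygons by sovereignty
#'
#' Groups polygon features into one region per distinct sovereignty label
#' (exact string match), mirroring a "dissolve by attribute" on an EEZ
#' shapefile. The partition preserves every input polygon.
#'
#' @param polygons List of [eez_polygon()].
#' @return List of `eez_region` objects (fields `country`, `polygons`),
#'   one per distinct label, in first-appearance order.
#' @export
merge_by_sovereignty <- function(polygons) {
  stopifnot(all(vapply(polygons, inherits, logical(1), "eez_polygon")))
  labs <- vapply(polygons, `[[`, character(1), "sovereignty")
  out <- lapply(unique(labs), function(s) {
    structure(list(country = s, polygons = polygons[labs == s]),
              class = "eez_region")
  })
  out
}

# --- planar geometry helpers (lon/lat degrees) ------------------------------

# Split a ring at the +-180 meridian. Returns a list of rings, none of which
# crosses the antimeridian, with longitudes renormalized to [-180, 180).
split_antimeridian <- function(ring) {
  lon <- ring[, 1L]
  d <- diff(lon)
  if (!any(abs(d) > 180)) return(list(ring))
  # unwrap to a continuous longitude track
  step <- d
  step[step > 180] <- step[step > 180] - 360
  step[step < -180] <- step[step < -180] + 360
  lon_u <- cumsum(c(lon[1L], step))
  r <- cbind(lon_u, ring[, 2L])
  # clip at every 180 + 360k boundary inside the unwrapped range
  bounds <- 180 + 360 * seq(floor((min(lon_u) - 180) / 360),
                            ceiling((max(lon_u) - 180) / 360))
  bounds <- bounds[bounds > min(lon_u) & bounds < max(lon_u)]
  parts <- list(r)
  for (b in bounds) {
    parts <- unlist(lapply(parts, function(p) {
      list(clip_halfplane(p, b, keep_left = TRUE),
           clip_halfplane(p, b, keep_left = FALSE))
    }), recursive = FALSE)
    parts <- Filter(function(p) !is.null(p) && nrow(p) >= 3L, parts)
  }
  # shift each part rigidly so its midpoint lies in [-180, 180); vertices
  # exactly on the cut stay at +-180 and never re-create a crossing
  lapply(parts, function(p) {
    k <- floor((mean(range(p[, 1L])) + 180) / 360)
    p[, 1L] <- p[, 1L] - 360 * k
    p
  })
}

# Sutherland-Hodgman clip of a ring against the vertical line lon = b.
clip_halfplane <- function(ring, b, keep_left) {
  n <- nrow(ring)
  sgn <- if (keep_left) 1 else -1
  inside <- sgn * (b - ring[, 1L]) >= 0
  out <- matrix(numeric(0), 0L, 2L)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    p1 <- ring[k, ]; p2 <- ring[k2, ]
    if (inside[k]) out <- rbind(out, p1)
    if (inside[k] != inside[k2]) {
      t <- (b - p1[1L]) / (p2[1L] - p1[1L])
      out <- rbind(out, c(b, p1[2L] + t * (p2[2L] - p1[2L])))
    }
  }
  if (nrow(out) < 3L) return(NULL)
  out
}

# Even-odd point-in-ring test, vectorized over points; boundary counts inside.
point_in_ring <- function(px, py, ring, eps = 1e-9) {
  n <- nrow(ring)
  xs <- ring[, 1L]; ys <- ring[, 2L]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    x1 <- xs[k]; y1 <- ys[k]; x2 <- xs[k2]; y2 <- ys[k2]
    crs <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on_edge <- on_edge |
      (abs(crs) <= eps * (abs(x2 - x1) + abs(y2 - y1) + 1) &
         px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
         py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps)
    crossing <- (y1 > py) != (y2 > py)
    if (any(crossing)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crossing & px < xint)
    }
  }
  inside | on_edge
}

ring_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  abs(sum(x * y2 - x2 * y)) / 2
}

# Circular-mean centroid of all ring vertices of a region.
region_centroid <- function(region) {
  v <- do.call(rbind, unlist(lapply(region$polygons, `[[`, "rings"),
                             recursive = FALSE))
  th <- v[, 1L] * pi / 180
  lon <- atan2(mean(sin(th)), mean(cos(th))) * 180 / pi
  c(lon = lon, lat = mean(v[, 2L]))
}

#' Grid cells inside an EEZ region
#'
#' Tests every grid-cell center against the region's polygon union with the
#' even-odd rule; centers on a polygon boundary count as inside. Rings that
#' cross the antimeridian are split at +-180 degrees before testing.
#' Zero-area (degenerate) regions yield an empty set with attribute
#' `degenerate = TRUE`.
#'
#' @param region An `eez_region` from [merge_by_sovereignty()].
#' @param grid A [grid_spec()].
#' @return Integer matrix with columns `i` (lat index), `j` (lon index).
#' @export
cells_in_region <- function(region, grid) {
  stopifnot(inherits(region, "eez_region"), inherits(grid, "grid_spec"))
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  hit <- matrix(FALSE, nlat, nlon)
  any_area <- FALSE
  for (poly in region$polygons) {
    parity <- matrix(0L, nlat, nlon)
    for (ring in poly$rings) {
      for (part in split_antimeridian(ring)) {
        if (ring_area(part) <= 1e-12) next
        any_area <- TRUE
        jj <- which(grid$lon >= min(part[, 1L]) - 1e-9 &
                      grid$lon <= max(part[, 1L]) + 1e-9)
        ii <- which(grid$lat >= min(part[, 2L]) - 1e-9 &
                      grid$lat <= max(part[, 2L]) + 1e-9)
        if (!length(ii) || !length(jj)) next
        px <- rep(grid$lon[jj], each = length(ii))
        py <- rep(grid$lat[ii], length(jj))
        ok <- point_in_ring(px, py, part)
        parity[cbind(rep(ii, length(jj)), rep(jj, each = length(ii)))] <-
          parity[cbind(rep(ii, length(jj)), rep(jj, each = length(ii)))] +
          as.integer(ok)
      }
    }
    hit <- hit | (parity %% 2L == 1L)
  }
  idx <- which(hit, arr.ind = TRUE)
  out <- cbind(i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]))
  attr(out, "degenerate") <- !any_area
  out
}

#' Zonal mean anomaly over one EEZ region
#'
#' Unweighted mean of the anomaly field over the grid cells whose centers
#' fall inside the region. Small regions that contain no cell center (or
#' only missing cells) fall back to the single valid cell nearest the
#' region centroid; if no valid cell lies within `fallback_radius` degrees,
#' the country is marked `excluded` (missing exposure).
#'
#' @param anom An [anomaly()] field.
#' @param region An `eez_region`.
#' @param fallback_radius Search radius for the nearest-cell fallback,
#'   degrees (default 5).
#' @return List of class `zonal_result`: `country`, `mean` (delta degC),
#'   `n_cells`, `fallback`, `excluded`.
#' @export
zonal_mean <- function(anom, region, fallback_radius = 5) {
  stopifnot(inherits(anom, "anomaly_field"))
  cells <- cells_in_region(region, anom$grid)
  vals <- if (nrow(cells)) anom$values[cells] else numeric(0)
  vals <- vals[is.finite(vals)]
  if (length(vals)) {
    return(structure(list(country = region$country, mean = mean(vals),
                          n_cells = length(vals), fallback = FALSE,
                          excluded = FALSE), class = "zonal_result"))
  }
  ctr <- region_centroid(region)
  dlon <- abs(outer(rep(1, length(anom$grid$lat)), anom$grid$lon) - ctr["lon"])
  dlon <- pmin(dlon, 360 - dlon)
  dlat <- abs(outer(anom$grid$lat, rep(1, length(anom$grid$lon))) - ctr["lat"])
  dist <- sqrt(dlon^2 + dlat^2)
  dist[!is.finite(anom$values)] <- Inf
  k <- which.min(dist)
  if (is.finite(dist[k]) && dist[k] <= fallback_radius) {
    structure(list(country = region$country, mean = anom$values[k],
                   n_cells = 1L, fallback = TRUE, excluded = FALSE),
              class = "zonal_result")
  } else {
    structure(list(country = region$country, mean = NA_real_, n_cells = 0L,
                   fallback = FALSE, excluded = TRUE), class = "zonal_result")
  }
}

#' Per-country exposure table for one anomaly field
#'
#' Applies [zonal_mean()] to every region and assembles the E1 table.
#'
#' @param anom An [anomaly()] field.
#' @param regions List of `eez_region`.
#' @return data.frame with columns `country`, `rcp`, `window`,
#'   `anomaly_degC`, `n_cells`, `fallback`, `excluded`.
#' @export
zonal_means <- function(anom, regions) {
  rows <- lapply(regions, function(rg) {
    z <- zonal_mean(anom, rg)
    data.frame(country = z$country, rcp = anom$scenario$rcp,
               window = paste(anom$scenario$window, collapse = "-"),
               anomaly_degC = z$mean, n_cells = z$n_cells,
               fallback = z$fallback, excluded = z$excluded,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
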