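#' @name gridded-csv
#' @title Plain-text gridded series format
#'
#' @description
#' A simple CSV dialect for monthly gridded fields: comment headers carry
#' the grid (`# lat:` / `# lon:` cell centers) and model label, then one
#' row per time step with columns `year`, `month` and one value column per
#' cell, latitude index varying slowest. Missing cells are empty fields.
#' Round-trips [gridded_series()] objects losslessly to printed precision.
NULL

.atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path, call. = FALSE)
  invisible(path)
}

#' @rdname gridded-csv
#' @param field A [gridded_series()].
#' @param path Output file path (written atomically).
#' @param digits Significant digits to print (default 10).
#' @export
write_gridded_csv <- function(field, path, digits = 10) {
  stopifnot(inherits(field, "gridded_series"))
  g <- field$grid
  nt <- length(field$year)
  ncell <- length(g$lat) * length(g$lon)
  # cell (i, j) -> column (i - 1) * nlon + j: latitude slowest
  v <- matrix(aperm(field$values, c(1L, 3L, 2L)), nrow = nt)
  .atomic_write(path, function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    writeLines(c("# gridded_series v1",
                 paste0("# model: ", field$model),
                 paste0("# lat: ", paste(format(g$lat, digits = 15,
                                                trim = TRUE),
                                         collapse = ",")),
                 paste0("# lon: ", paste(format(g$lon, digits = 15,
                                                trim = TRUE),
                                         collapse = ","))), con)
    df <- data.frame(year = field$year, month = field$month,
                     signif(v, digits))
    names(df) <- c("year", "month", sprintf("v%d", seq_len(ncell)))
    utils::write.table(df, con, sep = ",", row.names = FALSE,
                       quote = FALSE, na = "")
  })
}

#' @rdname gridded-csv
#' @return `read_gridded_csv()` returns a [gridded_series()].
#' @export
read_gridded_csv <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) stop("malformed gridded CSV: missing '# ", key,
                          ":' header", call. = FALSE)
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  lat <- as.numeric(strsplit(get("lat"), ",")[[1]])
  lon <- as.numeric(strsplit(get("lon"), ",")[[1]])
  model <- get("model")
  df <- utils::read.csv(path, comment.char = "#")
  grid <- grid_spec(lat, lon)
  nt <- nrow(df)
  v <- as.matrix(df[, -(1:2), drop = FALSE])
  if (ncol(v) != length(lat) * length(lon))
    stop("malformed gridded CSV: cell count does not match grid",
         call. = FALSE)
  # undo latitude-slowest column order
  arr <- array(NA_real_, c(nt, length(lat), length(lon)))
  for (i in seq_along(lat))
    arr[, i, ] <- v[, (i - 1L) * length(lon) + seq_along(lon)]
  gridded_series(grid, df$year, df$month, arr,
                 model = if (model == "NA") NA_character_ else model)
}

#' Write an anomaly field as CSV
#'
#' Long format: `lat`, `lon`, `sst_anomaly` (delta degC; missing cells
#' written as empty fields), with scenario metadata in comment headers.
#'
#' @param anom An [anomaly()] field.
#' @param path Output path.
#' @export
write_anomaly_csv <- function(anom, path) {
  stopifnot(inherits(anom, "anomaly_field"))
  g <- anom$grid
  df <- data.frame(lat = rep(g$lat, length(g$lon)),
                   lon = rep(g$lon, each = length(g$lat)),
                   sst_anomaly = as.vector(anom$values))
  .atomic_write(path, function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    writeLines(c(sprintf("# anomaly_field rcp=%.1f window=%d-%d n_models=%d",
                         anom$scenario$rcp, anom$scenario$window[1],
                         anom$scenario$window[2], anom$n_models)), con)
    utils::write.table(df, con, sep = ",", row.names = FALSE,
                       quote = FALSE, na = "")
  })
}

#' Read and write EEZ polygons as GeoJSON
#'
#' A `FeatureCollection` of `Polygon`/`MultiPolygon` features; the
#' sovereignty label is taken from a configurable property key (default
#' `"SOVEREIGN1"`, the usual attribute name in EEZ shapefile releases).
#'
#' @param path File path.
#' @param sovereignty_key Property name holding the sovereignty label.
#' @return `read_eez_geojson()` returns a list of [eez_polygon()].
#' @export
read_eez_geojson <- function(path, sovereignty_key = "SOVEREIGN1") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features))
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  polys <- list()
  for (ft in gj$features) {
    sov <- ft$properties[[sovereignty_key]]
    if (is.null(sov) || !nzchar(sov))
      stop("feature without sovereignty property '", sovereignty_key, "'",
           call. = FALSE)
    id <- if (!is.null(ft$id)) ft$id else
      if (!is.null(ft$properties$id)) ft$properties$id else
        length(polys) + 1L
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    gtype <- ft$geometry$type
    if (gtype == "Polygon") {
      polys[[length(polys) + 1L]] <-
        eez_polygon(id, sov, lapply(ft$geometry$coordinates, ring_mat))
    } else if (gtype == "MultiPolygon") {
      for (pp in seq_along(ft$geometry$coordinates))
        polys[[length(polys) + 1L]] <-
          eez_polygon(paste0(id, "-", pp), sov,
                      lapply(ft$geometry$coordinates[[pp]], ring_mat))
    } else stop("unsupported geometry type: ", gtype, call. = FALSE)
  }
  polys
}

#' @rdname read_eez_geojson
#' @param polygons List of [eez_polygon()].
#' @export
write_eez_geojson <- function(polygons, path,
                              sovereignty_key = "SOVEREIGN1") {
  feats <- lapply(polygons, function(p) {
    rings <- lapply(p$rings, function(r) {
      r <- rbind(r, r[1L, , drop = FALSE])  # GeoJSON rings are closed
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1L], r[k, 2L]))
    })
    list(type = "Feature",
         properties = stats::setNames(list(p$id, p$sovereignty),
                                      c("id", sovereignty_key)),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  .atomic_write(path, function(tmp)
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         tmp, auto_unbox = TRUE, digits = NA))
}

#' Raw country table schema
#'
#' @description
#' The raw country table is a CSV with one row per country and fixed
#' column names: identifiers and classifications (`country`, `name`,
#' `landlocked`, `ldc`, `oecd`, `sids`, `continent`), sensitivity inputs
#' (`n_fishers`, `econ_active_pop`, `fish_export_value`,
#' `total_export_value`, `landings_2012/2013/2014`,
#' `marine_fish_protein`, `total_protein`), adaptive-capacity inputs
#' (`subsidy_pct_y1/y2/y3`, `industrial_catch`, `smallscale_catch`,
#' `hale`, the six `gov_*` dimensions, `literacy_pct`, `enrolment_pct`,
#' `gdp_per_capita`) and optional `co2_per_capita`. Empty fields are
#' missing values. A spreadsheet export in another column naming can be
#' adapted via `col_map` (named character vector, `schema_name =
#' "file name"`).
#'
#' @param path CSV path.
#' @param col_map Optional renaming map applied after reading.
#' @return data.frame in the schema above.
#' @export
read_country_table <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map))
    for (k in names(col_map)) {
      if (!col_map[[k]] %in% names(df))
        stop("column mapping refers to absent column '", col_map[[k]], "'",
             call. = FALSE)
      names(df)[names(df) == col_map[[k]]] <- k
    }
  need <- c("country", "landlocked", "n_fishers", "econ_active_pop",
            "fish_export_value", "total_export_value", "landings_2012",
            "landings_2013", "landings_2014", "marine_fish_protein",
            "total_protein", "subsidy_pct_y1", "subsidy_pct_y2",
            "subsidy_pct_y3", "industrial_catch", "smallscale_catch",
            "hale", "gov_voice", "gov_stability", "gov_effectiveness",
            "gov_regulatory", "gov_rule_of_law", "gov_corruption",
            "literacy_pct", "enrolment_pct", "gdp_per_capita")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("country table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_country_table
#' @param records data.frame in the schema.
#' @export
write_country_table <- function(records, path) {
  .atomic_write(path, function(tmp)
    utils::write.csv(records, tmp, row.names = FALSE, na = ""))
}

#' Write a vulnerability table as CSV
#'
#' Scores are printed at 9 decimal places.
#' @param vt A [vulnerability_index()] table.
#' @param path Output path.
#' @export
write_index_csv <- function(vt, path) {
  out <- vt
  for (cn in c("E_N", "S_N", "AC_N", "V_raw", "V_N"))
    out[[cn]] <- sprintf("%.9f", out[[cn]])
  .atomic_write(path, function(tmp)
    utils::write.csv(out, tmp, row.names = FALSE, na = ""))
}

#' Read a run configuration
#'
#' JSON (always) or YAML (when the `yaml` package is installed) mapping of
#' paths, scenario selection, column mappings, flags and seed used by the
#' analysis drivers; values given as function arguments override file
#' values.
#'
#' @param path Config file, `.json`, `.yml` or `.yaml`.
#' @param ... Overrides.
#' @return Named list.
#' @export
read_run_config <- function(path, ...) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}
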