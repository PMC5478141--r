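#' Min-max normalization over the country set
#'
#' Linear rescaling `(x - min) / (max - min)` computed over the non-missing
#' values; missing values propagate. A constant vector has no information
#' and maps to 0.5 everywhere, with a warning.
#'
#' @param x Numeric vector (at least two non-missing values).
#' @return Numeric vector in `[0, 1]` with the `NA` pattern of `x`.
#' @export
minmax_normalize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L)
    stop("min-max normalization needs at least 2 non-missing values",
         call. = FALSE)
  lo <- min(x[ok]); hi <- max(x[ok])
  if (hi == lo) {
    warning("constant input to min-max normalization; returning 0.5",
            call. = FALSE)
    out <- x
    out[ok] <- 0.5
    return(out)
  }
  (x - lo) / (hi - lo)
}

#' Exposure index
#'
#' The normalized EEZ-mean SST anomaly (the single exposure variable).
#' @param e1 Per-country anomaly values, delta degC.
#' @return E_N in `[0, 1]`.
#' @export
exposure_index <- function(e1) minmax_normalize(e1)

#' Sensitivity index
#'
#' Each of the five sensitivity variables is min-max normalized, the five
#' are averaged with equal weights, and the aggregate is normalized again
#' over the country set.
#'
#' @param s A data.frame or matrix with columns S1..S5 (rows = countries).
#' @return S_N in `[0, 1]`.
#' @export
sensitivity_index <- function(s) {
  s <- as.matrix(s)
  stopifnot(ncol(s) == 5L)
  sn <- apply(s, 2L, minmax_normalize)
  minmax_normalize(rowMeans(sn))
}

#' Adaptive-capacity index
#'
#' Each of the six adaptive-capacity variables is min-max normalized (all
#' oriented so that larger values mean more capacity). The two
#' fisheries-specific variables (AC1 subsidies, AC2 industrial share) are
#' averaged to form one half of the index and the four broad socio-economic
#' variables (AC3 HALE, AC4 governance, AC5 education, AC6 GDP per capita)
#' the other half:
#' `AC = 0.5 * (mean(AC1_N, AC2_N) + mean(AC3_N, AC4_N, AC5_N, AC6_N))`,
#' which weights each fisheries variable twice as heavily as each
#' socio-economic one. The aggregate is normalized again.
#'
#' @param ac A data.frame or matrix with columns AC1..AC6.
#' @return AC_N in `[0, 1]`.
#' @export
adaptive_capacity_index <- function(ac) {
  ac <- as.matrix(ac)
  stopifnot(ncol(ac) == 6L)
  an <- apply(ac, 2L, minmax_normalize)
  raw <- 0.5 * (rowMeans(an[, 1:2, drop = FALSE]) +
                  rowMeans(an[, 3:6, drop = FALSE]))
  minmax_normalize(raw)
}

#' Quartile labels from ranks
#'
#' Contiguous rank blocks; when n is not divisible by 4 the earlier
#' quartiles take the remainder (n = 147 gives 37/37/37/36).
#'
#' @param rank Integer ranks in 1..n (1 = most vulnerable).
#' @param n Size of the full country set (default `length(rank)`).
#' @return Integer quartile labels 1..4.
#' @export
rank_quartiles <- function(rank, n = length(rank)) {
  base <- n %/% 4L
  sizes <- rep(base, 4L) + as.integer(seq_len(4L) <= n %% 4L)
  cuts <- cumsum(sizes)
  findInterval(rank, c(0L, cuts) + 0.5) |> as.integer()
}

#' Vulnerability table from the three component indices
#'
#' Combines the normalized components as
#' `V_raw = E_N + S_N - AC_N` (exposure plus sensitivity minus adaptive
#' capacity), normalizes the result over the country set, and attaches
#' descending ranks (1 = most vulnerable; ties broken alphabetically by
#' country key) and rank-block quartiles.
#'
#' @param country Character vector of country keys.
#' @param e_n,s_n,a_n Component indices aligned with `country`.
#' @param scenario Optional [scenario_spec()] recorded in the output.
#' @return data.frame of class `vulnerability_table`: `country`, `E_N`,
#'   `S_N`, `AC_N`, `V_raw`, `V_N`, `rank`, `quartile` (+ `rcp`, `window`
#'   when a scenario is given), sorted by rank.
#' @export
vulnerability_index <- function(country, e_n, s_n, a_n, scenario = NULL) {
  n <- length(country)
  if (length(e_n) != n || length(s_n) != n || length(a_n) != n)
    stop("component misalignment: unequal lengths", call. = FALSE)
  if (anyDuplicated(country))
    stop("component misalignment: duplicated country keys", call. = FALSE)
  v_raw <- e_n + s_n - a_n
  v_n <- minmax_normalize(v_raw)
  ord <- order(-v_n, country)
  rank <- integer(n); rank[ord] <- seq_len(n)
  out <- data.frame(country = country, E_N = e_n, S_N = s_n, AC_N = a_n,
                    V_raw = v_raw, V_N = v_n, rank = rank,
                    quartile = rank_quartiles(rank),
                    stringsAsFactors = FALSE)
  if (!is.null(scenario)) {
    out$rcp <- scenario$rcp
    out$window <- paste(scenario$window, collapse = "-")
  }
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("vulnerability_table", "data.frame")
  out
}

#' Compute the index for one scenario from an indicator matrix
#'
#' @param indicators data.frame with columns `country`, `E1`, `S1..S5`,
#'   `AC1..AC6` (complete cases).
#' @param scenario Optional [scenario_spec()].
#' @return A [vulnerability_index()] table.
#' @export
compute_index <- function(indicators, scenario = NULL) {
  need <- c("country", "E1", paste0("S", 1:5), paste0("AC", 1:6))
  miss <- setdiff(need, names(indicators))
  if (length(miss))
    stop("indicator table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  vulnerability_index(
    country = indicators$country,
    e_n = exposure_index(indicators$E1),
    s_n = sensitivity_index(indicators[, paste0("S", 1:5)]),
    a_n = adaptive_capacity_index(indicators[, paste0("AC", 1:6)]),
    scenario = scenario)
}

#' Run the index across scenarios
#'
#' One vulnerability table per scenario. Only the exposure variable differs
#' between scenarios; the sensitivity and adaptive-capacity columns are
#' identical across the returned tables by construction.
#'
#' @param socio data.frame with `country`, `S1..S5`, `AC1..AC6`.
#' @param e1_by_scenario Named list (by scenario label) of data.frames with
#'   `country`, `anomaly_degC`.
#' @param scenarios List of [scenario_spec()] aligned with
#'   `e1_by_scenario`; defaults to [scenario_grid()] entries matching the
#'   names.
#' @return Named list of [vulnerability_index()] tables. Scenarios whose
#'   anomaly table is absent are skipped with a warning.
#' @export
run_scenarios <- function(socio, e1_by_scenario,
                          scenarios = scenario_grid()[names(e1_by_scenario)]) {
  out <- list()
  for (nm in names(scenarios)) {
    e1 <- e1_by_scenario[[nm]]
    if (is.null(e1)) {
      warning("no anomaly table for scenario ", nm, "; skipped",
              call. = FALSE)
      next
    }
    m <- merge(socio, e1[, c("country", "anomaly_degC")], by = "country")
    m$E1 <- m$anomaly_degC
    out[[nm]] <- compute_index(m, scenario = scenarios[[nm]])
  }
  out
}
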