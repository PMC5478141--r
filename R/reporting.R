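#' Quartile cross-tabulation of a classification group
#'
#' Counts, per quartile, the members of each classification group (e.g.
#' LDC, OECD) for each of the four metrics E, S, AC and V. The E/S/AC
#' quartiles use the same contiguous rank-partition applied to each
#' component index that the vulnerability table uses for V.
#'
#' @param vt A [vulnerability_index()] table.
#' @param groups Named list of logical vectors (or character vectors of
#'   country keys) defining the groups, e.g.
#'   `list(LDC = c("A", "B"), OECD = ...)`.
#' @return data.frame with columns `quartile`, then `<group>.<metric>`
#'   count columns for metric in E, S, AC, V; each metric column sums to
#'   the group size.
#' @export
quartile_crosstab <- function(vt, groups) {
  n <- nrow(vt)
  qs <- list(
    E = rank_quartiles(component_ranks(vt$E_N, vt$country)),
    S = rank_quartiles(component_ranks(vt$S_N, vt$country)),
    AC = rank_quartiles(component_ranks(vt$AC_N, vt$country)),
    V = vt$quartile)
  out <- data.frame(quartile = 1:4)
  for (g in names(groups)) {
    memb <- groups[[g]]
    if (is.character(memb)) memb <- vt$country %in% memb
    if (length(memb) != n)
      stop("group membership must match the table's countries",
           call. = FALSE)
    for (m in names(qs))
      out[[paste(g, m, sep = ".")]] <-
        vapply(1:4, function(q) sum(memb & qs[[m]] == q), integer(1))
  }
  out
}

# Descending ranks of a component index, ties broken by country key.
component_ranks <- function(x, country) {
  ord <- order(-x, country)
  r <- integer(length(x)); r[ord] <- seq_along(x)
  r
}

#' Geographic cross-tabulation
#'
#' Counts countries per vulnerability quartile for each continent label.
#' Unlabelled countries are tallied under `"other"`.
#'
#' @param vt A [vulnerability_index()] table.
#' @param continent Character vector aligned with `vt$country` (or a named
#'   vector keyed by country).
#' @return data.frame: `quartile` rows 1..4 plus a `"total"` row; one
#'   column per continent. All cells sum to `nrow(vt)`.
#' @export
geography_crosstab <- function(vt, continent) {
  if (!is.null(names(continent))) continent <- continent[vt$country]
  continent <- as.character(continent)
  continent[is.na(continent) | !nzchar(continent)] <- "other"
  if (length(continent) != nrow(vt))
    stop("continent labels must match the table's countries", call. = FALSE)
  labs <- unique(continent)
  out <- data.frame(quartile = c(as.character(1:4), "total"))
  for (ct in labs) {
    cnt <- vapply(1:4, function(q) sum(continent == ct & vt$quartile == q),
                  integer(1))
    out[[ct]] <- c(cnt, sum(cnt))
  }
  out
}

#' Rank and product-moment correlation between two country variables
#'
#' Spearman's rho on average ranks (ties shared), Pearson's r and r^2 on
#' the raw values; incomplete pairs are dropped. Two-sided p-values use the
#' t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom for both coefficients.
#'
#' @param x,y Paired numeric vectors.
#' @return List of class `correlation_result`: `n`, `spearman_rho`,
#'   `spearman_p`, `pearson_r`, `pearson_p`, `r_squared`.
#' @export
rank_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in one variable; correlation undefined",
            call. = FALSE)
    return(structure(list(n = n, spearman_rho = NA_real_,
                          spearman_p = NA_real_, pearson_r = NA_real_,
                          pearson_p = NA_real_, r_squared = NA_real_),
                     class = "correlation_result"))
  }
  rho <- stats::cor(x, y, method = "spearman")
  r <- stats::cor(x, y, method = "pearson")
  pval <- function(cc) {
    if (abs(cc) >= 1) return(0)
    tt <- cc * sqrt((n - 2) / (1 - cc^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(n = n, spearman_rho = rho, spearman_p = pval(rho),
                 pearson_r = r, pearson_p = pval(r), r_squared = r^2),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("n = %d, Spearman rho = %.3f (p = %.2g), Pearson r = %.3f (p = %.2g), r^2 = %.3f\n",
              x$n, x$spearman_rho, x$spearman_p, x$pearson_r, x$pearson_p,
              x$r_squared))
  invisible(x)
}

#' Vulnerability vs per-capita carbon emissions
#'
#' Correlates the normalized vulnerability score with per-capita CO2
#' emissions and returns the scatter data (with LDC/OECD color classes)
#' alongside the correlation.
#'
#' @param vt A [vulnerability_index()] table.
#' @param co2_per_capita Named numeric vector (metric tons per capita)
#'   keyed by country, or a vector aligned with `vt$country`.
#' @param ldc,oecd Character vectors of country keys (optional, for the
#'   scatter classes).
#' @return List: `correlation` (a [rank_correlation()] result) and
#'   `scatter` (data.frame `country`, `V_N`, `co2_per_capita`, `class`).
#' @export
emissions_correlation <- function(vt, co2_per_capita, ldc = character(0),
                                  oecd = character(0)) {
  co2 <- if (!is.null(names(co2_per_capita)))
    unname(co2_per_capita[vt$country]) else co2_per_capita
  cls <- ifelse(vt$country %in% ldc, "LDC",
                ifelse(vt$country %in% oecd, "OECD", "other"))
  list(correlation = rank_correlation(vt$V_N, co2),
       scatter = data.frame(country = vt$country, V_N = vt$V_N,
                            co2_per_capita = co2, class = cls,
                            stringsAsFactors = FALSE))
}

#' Most and least vulnerable countries per scenario
#'
#' @param tables Named list of [vulnerability_index()] tables.
#' @param k Head/tail size (default 5).
#' @param sids,oecd Character vectors of country keys used for annotation.
#' @return data.frame: `scenario`, `end` ("most"/"least"), `rank`,
#'   `country`, `V_N`, `annotation` ("SIDS", "OECD" or "").
#' @export
scenario_extremes <- function(tables, k = 5L, sids = character(0),
                              oecd = character(0)) {
  rows <- lapply(names(tables), function(nm) {
    vt <- tables[[nm]][order(tables[[nm]]$rank), ]
    n <- nrow(vt)
    pick <- rbind(
      data.frame(end = "most", idx = seq_len(min(k, n))),
      data.frame(end = "least", idx = seq(max(n - k + 1L, 1L), n)))
    data.frame(scenario = nm, end = pick$end, rank = vt$rank[pick$idx],
               country = vt$country[pick$idx], V_N = vt$V_N[pick$idx],
               annotation = ifelse(vt$country[pick$idx] %in% sids, "SIDS",
                                   ifelse(vt$country[pick$idx] %in% oecd,
                                          "OECD", "")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Share of a group in the top half of the index
#'
#' @param vt A [vulnerability_index()] table.
#' @param members Character vector of country keys.
#' @return Fraction of `members` (present in the table) with quartile 1 or 2.
#' @export
top_half_share <- function(vt, members) {
  memb <- vt$country %in% members
  if (!any(memb)) return(NA_real_)
  sum(memb & vt$quartile <= 2L) / sum(memb)
}
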