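#' @name indicator-derivations
#' @title Socio-economic indicator derivations
#'
#' @description
#' Small derivation rules turning raw country statistics into the eleven
#' socio-economic analysis variables: five sensitivity variables (S1
#' fishers, S2 export share, S3 fisher share of the economically active
#' population, S4 mean landings 2012--2014, S5 fish-protein share) and six
#' adaptive-capacity variables (AC1 subsidy intensity, AC2 industrial share
#' of catch, AC3 healthy life expectancy, AC4 governance mean, AC5
#' education, AC6 GDP per capita). Each returns `NA` when its inputs do not
#' permit the derivation; shares are clamped to `[0, 1]` with a warning
#' when raw ratios exceed 1.
NULL

#' @describeIn indicator-derivations S2: fisheries exports as a fraction of
#'   total exports.
#' @param fish_export_value,total_export_value Export values, same currency.
#' @export
export_share <- function(fish_export_value, total_export_value) {
  if (is.na(total_export_value) || total_export_value <= 0 ||
      is.na(fish_export_value)) return(NA_real_)
  r <- fish_export_value / total_export_value
  if (r > 1) {
    warning("fisheries exports exceed total exports; share clamped to 1",
            call. = FALSE)
    r <- 1
  }
  max(r, 0)
}

#' @describeIn indicator-derivations S4: mean of landings over the years
#'   2012--2014 that are reported.
#' @param landings_by_year Numeric vector (tons) for 2012, 2013, 2014;
#'   `NA` for unreported years.
#' @export
landings_mean <- function(landings_by_year) {
  x <- landings_by_year[!is.na(landings_by_year)]
  if (!length(x)) return(NA_real_)
  mean(x)
}

#' @describeIn indicator-derivations S5: marine fish protein as a fraction
#'   of total protein consumption.
#' @param marine_fish_protein,total_protein g/capita/day.
#' @export
protein_share <- function(marine_fish_protein, total_protein) {
  if (is.na(total_protein) || total_protein <= 0 ||
      is.na(marine_fish_protein)) return(NA_real_)
  r <- marine_fish_protein / total_protein
  if (r > 1) {
    warning("marine protein exceeds total protein; share clamped to 1",
            call. = FALSE)
    r <- 1
  }
  max(r, 0)
}

#' @describeIn indicator-derivations S3: fishers as a fraction of the
#'   economically active population.
#' @param n_fishers,econ_active_pop Persons.
#' @export
fisher_share <- function(n_fishers, econ_active_pop) {
  if (is.na(econ_active_pop) || econ_active_pop <= 0 ||
      is.na(n_fishers)) return(NA_real_)
  r <- n_fishers / econ_active_pop
  if (r > 1) {
    warning("fishers exceed economically active population; clamped to 1",
            call. = FALSE)
    r <- 1
  }
  max(r, 0)
}

#' @describeIn indicator-derivations AC1: fisheries subsidies as percent of
#'   landed value, averaged over the years reported.
#' @param subsidy_pct_by_year Numeric vector of yearly percentages.
#' @export
subsidy_intensity <- function(subsidy_pct_by_year) {
  x <- subsidy_pct_by_year[!is.na(subsidy_pct_by_year)]
  if (!length(x)) return(NA_real_)
  mean(x)
}

#' @describeIn indicator-derivations AC2: industrial catch as a fraction of
#'   total (industrial + small-scale) catch -- a bounded, order-preserving
#'   transform of the industrial:small-scale ratio.
#' @param industrial_catch,smallscale_catch Tons.
#' @param mode `"share"` (default) or `"ratio"` for the literal unbounded
#'   industrial / small-scale ratio.
#' @export
industrial_share <- function(industrial_catch, smallscale_catch,
                             mode = c("share", "ratio")) {
  mode <- match.arg(mode)
  if (is.na(industrial_catch) || is.na(smallscale_catch)) return(NA_real_)
  tot <- industrial_catch + smallscale_catch
  if (tot <= 0) return(NA_real_)
  if (mode == "ratio") {
    if (smallscale_catch <= 0) return(NA_real_)
    return(industrial_catch / smallscale_catch)
  }
  industrial_catch / tot
}

#' @describeIn indicator-derivations AC4: unweighted mean of the six
#'   Worldwide Governance Indicators dimensions; at least four must be
#'   present.
#' @param governance_dims Numeric vector of up to six dimension scores.
#' @export
governance_score <- function(governance_dims) {
  x <- governance_dims[!is.na(governance_dims)]
  if (length(x) < 4L) return(NA_real_)
  mean(x)
}

#' @describeIn indicator-derivations AC5: adult literacy rate, with primary
#'   school enrolment filling gaps (the two are nearly collinear across
#'   countries reporting both).
#' @param literacy_pct,enrolment_pct Percentages.
#' @return `education_fill()` returns a list with `value` and `source`
#'   (`"literacy"` or `"enrolment"`); the other derivations return scalars.
#' @export
education_fill <- function(literacy_pct, enrolment_pct) {
  if (!is.na(literacy_pct))
    return(list(value = literacy_pct, source = "literacy"))
  if (!is.na(enrolment_pct))
    return(list(value = enrolment_pct, source = "enrolment"))
  list(value = NA_real_, source = NA_character_)
}

#' Assemble the indicator vector for one country
#'
#' Applies every derivation rule to a raw country record and attaches the
#' country's EEZ-mean SST anomaly as the exposure variable E1. Landlocked
#' countries are rejected (they have no marine exposure), as are countries
#' whose exposure could not be computed.
#'
#' @param rec One-row data.frame (or list) in the raw country schema; see
#'   [read_country_table()] for column names.
#' @param e1 A `zonal_result` for the country, or a bare anomaly value.
#' @return List of class `indicator_vector`: `country`, the named numeric
#'   `values` (E1, S1..S5, AC1..AC6), logical `complete` mask of the same
#'   names, `education_source`, `excluded`, `exclusion_reason`.
#' @export
build_indicator_vector <- function(rec, e1) {
  excl <- function(reason)
    structure(list(country = rec$country, values = NULL, complete = NULL,
                   education_source = NA_character_, excluded = TRUE,
                   exclusion_reason = reason),
              class = "indicator_vector")
  if (isTRUE(as.logical(rec$landlocked))) return(excl("landlocked"))
  e1v <- if (inherits(e1, "zonal_result")) {
    if (isTRUE(e1$excluded)) NA_real_ else e1$mean
  } else as.numeric(e1)
  if (is.na(e1v)) return(excl("missing exposure"))
  edu <- education_fill(rec$literacy_pct, rec$enrolment_pct)
  vals <- c(
    E1 = e1v,
    S1 = if (is.na(rec$n_fishers)) NA_real_ else as.numeric(rec$n_fishers),
    S2 = export_share(rec$fish_export_value, rec$total_export_value),
    S3 = fisher_share(rec$n_fishers, rec$econ_active_pop),
    S4 = landings_mean(c(rec$landings_2012, rec$landings_2013,
                         rec$landings_2014)),
    S5 = protein_share(rec$marine_fish_protein, rec$total_protein),
    AC1 = subsidy_intensity(c(rec$subsidy_pct_y1, rec$subsidy_pct_y2,
                              rec$subsidy_pct_y3)),
    AC2 = industrial_share(rec$industrial_catch, rec$smallscale_catch),
    AC3 = if (is.na(rec$hale)) NA_real_ else as.numeric(rec$hale),
    AC4 = governance_score(c(rec$gov_voice, rec$gov_stability,
                             rec$gov_effectiveness, rec$gov_regulatory,
                             rec$gov_rule_of_law, rec$gov_corruption)),
    AC5 = edu$value,
    AC6 = if (is.na(rec$gdp_per_capita)) NA_real_
          else as.numeric(rec$gdp_per_capita))
  structure(list(country = rec$country, values = vals,
                 complete = !is.na(vals), education_source = edu$source,
                 excluded = FALSE, exclusion_reason = NA_character_),
            class = "indicator_vector")
}

#' Indicator matrix for a country table
#'
#' Runs [build_indicator_vector()] over every row of a raw country table
#' joined with its exposure results, then applies the exclusion policy:
#' landlocked and missing-exposure countries are always dropped;
#' `"complete_case"` (default) additionally drops any country with a
#' missing analysis variable, so the later min-max normalizations see a
#' complete matrix.
#'
#' @param records data.frame in the raw country schema.
#' @param e1_table data.frame from [zonal_means()] (or with columns
#'   `country`, `anomaly_degC`, `excluded`).
#' @param policy `"complete_case"` or `"available_case"` (keep countries
#'   with gaps; downstream averaging then renormalizes over available
#'   variables).
#' @return List with `indicators` (data.frame: `country`, E1, S1..AC6),
#'   `completeness` (logical matrix), and `exclusions` (data.frame
#'   `country`, `reason`).
#' @export
build_indicator_table <- function(records, e1_table,
                                  policy = c("complete_case",
                                             "available_case")) {
  policy <- match.arg(policy)
  e1_map <- stats::setNames(
    ifelse(e1_table$excluded, NA_real_, e1_table$anomaly_degC),
    e1_table$country)
  rows <- list(); excl <- list(); comp <- list()
  for (k in seq_len(nrow(records))) {
    rec <- records[k, , drop = FALSE]
    iv <- build_indicator_vector(
      rec, if (rec$country %in% names(e1_map)) e1_map[[rec$country]]
           else NA_real_)
    if (iv$excluded) {
      excl[[length(excl) + 1L]] <-
        data.frame(country = iv$country, reason = iv$exclusion_reason,
                   stringsAsFactors = FALSE)
      next
    }
    if (policy == "complete_case" && !all(iv$complete)) {
      excl[[length(excl) + 1L]] <- data.frame(
        country = iv$country,
        reason = paste0("missing ",
                        paste(names(iv$values)[!iv$complete],
                              collapse = ",")),
        stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(country = iv$country, t(iv$values),
                 stringsAsFactors = FALSE)
    comp[[length(comp) + 1L]] <- iv$complete
  }
  ind <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(numeric(0), 0, 13)),
                    c("country", "E1", paste0("S", 1:5), paste0("AC", 1:6)))
  list(indicators = ind,
       completeness = if (length(comp)) do.call(rbind, comp) else NULL,
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(country = character(0), reason = character(0)))
}
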