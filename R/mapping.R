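#' Trial density per million inhabitants
#'
#' @param n_trials Number of trials (vectorized).
#' @param population Population in persons; must be positive.
#' @return Trials per million inhabitants.
#' @export
#' @examples
#' trial_density(6457, 10e6) # 645.7
trial_density <- function(n_trials, population) {
  if (any(population <= 0)) stop("population must be positive")
  n_trials * 1e6 / population
}

#' Per-country trial counts and densities
#'
#' Counts trials per country location — an international trial contributes
#' one count to each of its countries — and converts to trials per million
#' inhabitants. Density is considered meaningful only in countries with more
#' than 250,000 inhabitants (`eligible`).
#'
#' @param trials Filtered trial tibble.
#' @param countries Country reference table.
#' @param sponsor Optional sponsor type (`"industry"` or `"non_industry"`)
#'   to restrict the count.
#' @param international Optional logical: `TRUE` counts only international
#'   trials, `FALSE` only single-country trials.
#' @return Tibble with one row per reference country: `country`, `n_trials`,
#'   `density`, `eligible`, plus the country metadata columns.
#' @export
density_table <- function(trials, countries = country_table(), sponsor = NULL,
                          international = NULL) {
  sub <- restrict_trials(trials, sponsor, international)
  counts <- tibble::tibble(country = unlist(sub$countries, use.names = FALSE)) |>
    dplyr::count(.data$country, name = "n_trials")
  countries |>
    dplyr::rename(country = "code") |>
    dplyr::left_join(counts, by = "country") |>
    dplyr::mutate(
      n_trials = dplyr::coalesce(.data$n_trials, 0L),
      density = trial_density(.data$n_trials, .data$population_2012),
      eligible = .data$population_2012 > 250000
    ) |>
    dplyr::select("country", "n_trials", "density", "eligible",
                  "population_2012", "income_group", "region", "continent")
}

restrict_trials <- function(trials, sponsor = NULL, international = NULL) {
  if (!is.null(sponsor)) {
    sponsor <- match.arg(sponsor, c("industry", "non_industry"))
    trials <- trials[trials$sponsor_type == sponsor, , drop = FALSE]
  }
  if (!is.null(international)) {
    trials <- trials[(lengths(trials$countries) >= 2) == international, , drop = FALSE]
  }
  trials
}

#' Median trial density by income group or region
#'
#' Medians are taken across countries within each group, treating countries
#' equally (no population weighting); only countries passing the population
#' eligibility threshold contribute. Groups with no eligible country are
#' absent from the result rather than reported as zero.
#'
#' @param densities Output of [density_table()].
#' @param by Grouping column: `"income_group"` or `"region"`.
#' @return Tibble with the grouping column and `median_density`.
#' @export
group_median_density <- function(densities, by = c("income_group", "region")) {
  by <- match.arg(by)
  densities |>
    dplyr::filter(.data$eligible) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(median_density = stats::median(.data$density),
                     n_countries = dplyr::n(), .groups = "drop")
}

#' Classify the geographic scope of each trial
#'
#' A trial in one country is `single_country`; an international trial whose
#' countries all share a continent is `international_unicontinental`,
#' otherwise `international_intercontinental`.
#'
#' @param trials Trial tibble.
#' @param countries Country reference table.
#' @return `trials` with an added factor column `scope`.
#' @export
classify_scope <- function(trials, countries = country_table()) {
  continent <- stats::setNames(countries$continent, countries$code)
  scope <- purrr::map_chr(trials$countries, function(cc) {
    cont <- continent[cc]
    if (anyNA(cont)) {
      stop("countries without a continent assignment: ",
           paste(cc[is.na(cont)], collapse = ", "))
    }
    if (length(cc) <= 1) "single_country"
    else if (length(unique(cont)) == 1) "international_unicontinental"
    else "international_intercontinental"
  })
  trials$scope <- factor(scope, levels = c("single_country",
                                           "international_unicontinental",
                                           "international_intercontinental"))
  trials
}

#' Per-country share of industry sponsorship
#'
#' For each country, the share of trials conducted there (the country being
#' among the locations) that are industry-sponsored. Shares are flagged
#' `reportable` only where the country hosted at least 50 trials, the
#' denominator below which per-country proportions are considered unstable.
#'
#' @param trials Filtered trial tibble.
#' @param countries Country reference table.
#' @param min_trials Reportability threshold on the denominator.
#' @return Tibble: `country`, `numerator`, `denominator`, `share`,
#'   `reportable`.
#' @export
sponsorship_share <- function(trials, countries = country_table(), min_trials = 50) {
  long <- tidyr::unnest(
    trials[, c("trial_id", "sponsor_type", "countries")],
    "countries"
  )
  long |>
    dplyr::group_by(country = .data$countries) |>
    dplyr::summarise(
      numerator = sum(.data$sponsor_type == "industry"),
      denominator = dplyr::n(), .groups = "drop"
    ) |>
    finish_share(min_trials)
}

#' Per-country share of international trials
#'
#' For each country and one sponsor type, the share of that sponsor's trials
#' conducted there that are international (at least two countries). The
#' 50-trial reportability rule applies to the sponsor-specific denominator.
#'
#' @inheritParams sponsorship_share
#' @param sponsor `"industry"` or `"non_industry"`.
#' @return Tibble: `country`, `numerator`, `denominator`, `share`,
#'   `reportable`.
#' @export
international_share <- function(trials, sponsor, countries = country_table(),
                                min_trials = 50) {
  sponsor <- match.arg(sponsor, c("industry", "non_industry"))
  sub <- restrict_trials(trials, sponsor)
  sub$is_international <- lengths(sub$countries) >= 2
  long <- tidyr::unnest(sub[, c("trial_id", "is_international", "countries")],
                        "countries")
  long |>
    dplyr::group_by(country = .data$countries) |>
    dplyr::summarise(
      numerator = sum(.data$is_international),
      denominator = dplyr::n(), .groups = "drop"
    ) |>
    finish_share(min_trials)
}

finish_share <- function(tbl, min_trials) {
  tbl |>
    dplyr::mutate(
      share = ifelse(.data$denominator > 0, .data$numerator / .data$denominator, NA_real_),
      reportable = .data$denominator >= min_trials
    )
}

#' Annual distribution of trial locations by region or income group
#'
#' For each year, every country location of every trial counts once — a
#' trial run simultaneously in two South American countries counts twice
#' toward South America — and counts are normalized to shares within the
#' year.
#'
#' @param trials Filtered trial tibble.
#' @param years Years to tabulate; the default stops at 2012 because
#'   retrospective registration makes the final registry year incomplete.
#' @param by Grouping: `"region"` or `"income_group"`.
#' @param sponsor Optional sponsor type restriction.
#' @param countries Country reference table.
#' @return Tibble: `year`, group column, `n_locations`, `share`; shares sum
#'   to 1 within each year.
#' @export
annual_distribution <- function(trials, years = 2006:2012,
                                by = c("region", "income_group"),
                                sponsor = NULL, countries = country_table()) {
  by <- match.arg(by)
  sub <- restrict_trials(trials, sponsor)
  sub <- sub[sub$start_year %in% years, , drop = FALSE]
  long <- tidyr::unnest(sub[, c("trial_id", "start_year", "countries")], "countries")
  long <- dplyr::left_join(long,
                           dplyr::select(dplyr::rename(countries, countries = "code"),
                                         "countries", dplyr::all_of(by)),
                           by = "countries")
  long |>
    dplyr::count(year = .data$start_year, dplyr::across(dplyr::all_of(by)),
                 name = "n_locations") |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(share = .data$n_locations / sum(.data$n_locations)) |>
    dplyr::ungroup()
}
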