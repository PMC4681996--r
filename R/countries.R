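#' Bundled country reference table
#'
#' Returns the per-country metadata used throughout the package: 2012
#' population, World Bank income group (`high`, `upper_middle`,
#' `lower_middle`, `low`), geographic region and continent. The table ships
#' with the package as a plain CSV and covers 40 countries spanning all
#' income groups and regions; it is a synthetic-but-realistic stand-in for a
#' full World Bank extract and can be replaced by any table with the same
#' columns. Transcontinental countries carry a single continent assignment
#' (e.g. Russia is tabulated under Europe, Turkey under Asia); edit the CSV
#' to change that convention.
#'
#' @param path Optional path to an alternative CSV with columns `code`,
#'   `name`, `population_2012`, `income_group`, `region`, `continent`.
#' @return A tibble with one row per country.
#' @export
#' @examples
#' country_table()
country_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "countries.csv", package = "trialscape")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("code", "name", "population_2012", "income_group", "region", "continent")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("country table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tbl$code)) stop("country table has duplicated codes")
  if (any(tbl$population_2012 <= 0)) stop("country populations must be positive")
  tbl$income_group <- factor(tbl$income_group, levels = income_group_levels())
  if (anyNA(tbl$income_group)) stop("unknown income group in country table")
  tbl
}

income_group_levels <- function() c("high", "upper_middle", "lower_middle", "low")

region_levels <- function() {
  c("Western Europe", "Eastern Europe", "North America", "South America",
    "Asia", "Africa", "Oceania")
}

# Common registry spellings that differ from the reference table's names.
country_aliases <- function() {
  tibble::tibble(
    alias = c(
      "usa", "united states of america", "u.s.a.", "uk", "great britain",
      "korea, republic of", "republic of korea", "korea",
      "russian federation", "czechia", "tanzania, united republic of",
      "viet nam", "the netherlands", "holland"
    ),
    code = c(
      "US", "US", "US", "GB", "GB",
      "KR", "KR", "KR",
      "RU", "CZ", "TZ",
      "VN", "NL", "NL"
    )
  )
}

#' Resolve country names or codes to ISO 3166-1 alpha-2 codes
#'
#' Matches case-insensitively against ISO codes, full names from the country
#' table, and a small list of common registry spellings ("USA", "Russian
#' Federation", ...). Unresolvable values come back as `NA`.
#'
#' @param x Character vector of country names or codes.
#' @param countries Country reference table, see [country_table()].
#' @param extra_aliases Optional tibble with columns `alias` and `code`
#'   extending the built-in alias list.
#' @return Character vector of ISO codes with `NA` for unresolved entries.
#' @export
resolve_country <- function(x, countries = country_table(), extra_aliases = NULL) {
  key <- tolower(trimws(x))
  lookup <- c(
    stats::setNames(countries$code, tolower(countries$code)),
    stats::setNames(countries$code, tolower(countries$name))
  )
  al <- country_aliases()
  if (!is.null(extra_aliases)) al <- dplyr::bind_rows(al, extra_aliases)
  lookup <- c(lookup, stats::setNames(al$code, tolower(al$alias)))
  out <- unname(lookup[key])
  # only accept codes present in the reference table
  out[!out %in% countries$code] <- NA_character_
  out
}
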