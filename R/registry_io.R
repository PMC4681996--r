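#' Default sponsor keyword configuration
#'
#' Primary sponsors are classified as industry or non-industry by
#' case-insensitive keyword matching against the sponsor name, the approach
#' registries themselves suggest when no structured sponsor-type field is
#' available. Matching respects word boundaries, so "Inc" matches
#' "Acme Inc." but not "Incidence Study Group". A name matching keywords
#' from both lists (or neither) is classified `unknown`.
#'
#' The shipped lists are deliberately short and editable: corporate suffixes
#' and pharma vocabulary on the industry side, academic and public-sector
#' vocabulary on the non-industry side. Deliberately ambiguous words such as
#' "Foundation" (carried by both charities and corporate foundations) are
#' left off both lists, so such sponsors classify as `unknown` unless the
#' caller extends a list.
#'
#' @param industry,non_industry Character vectors of keywords. The two lists
#'   must be disjoint (after case folding and stripping trailing dots).
#' @return An object of class `sponsor_keywords`.
#' @export
#' @examples
#' classify_sponsor("Acme Pharma Inc.", sponsor_keywords())
sponsor_keywords <- function(
    industry = c("Ltd.", "Inc.", "LLC", "GmbH", "Corp.", "Pharma",
                 "Pharmaceuticals", "Biotech", "S.A."),
    non_industry = c("University", "Hospital", "Institute", "Ministry",
                     "Council", "College")) {
  norm <- function(k) tolower(sub("\\.+$", "", trimws(k)))
  if (length(intersect(norm(industry), norm(non_industry))) > 0) {
    stop("industry and non-industry keyword lists must be disjoint")
  }
  structure(list(industry = industry, non_industry = non_industry),
            class = "sponsor_keywords")
}

keyword_regex <- function(keys) {
  stripped <- sub("\\.+$", "", trimws(keys))
  escaped <- stringr::str_replace_all(stripped, "([\\W])", "\\\\\\1")
  paste0("\\b(", paste(escaped, collapse = "|"), ")\\b")
}

#' Classify a primary sponsor as industry or non-industry
#'
#' @param sponsor_name Character vector of free-text sponsor names (may
#'   contain `NA` or empty strings).
#' @param config Keyword configuration from [sponsor_keywords()].
#' @return Factor with levels `industry`, `non_industry`, `unknown`.
#'   `unknown` marks names where no keyword matched or both lists matched.
#' @export
#' @examples
#' classify_sponsor(c("Acme Pharma Inc.", "University of Somewhere", "Zorblat 42"))
classify_sponsor <- function(sponsor_name, config = sponsor_keywords()) {
  stopifnot(inherits(config, "sponsor_keywords"))
  x <- tolower(trimws(as.character(sponsor_name)))
  ind <- stringr::str_detect(x, stringr::regex(keyword_regex(config$industry), ignore_case = TRUE))
  non <- stringr::str_detect(x, stringr::regex(keyword_regex(config$non_industry), ignore_case = TRUE))
  ind[is.na(ind)] <- FALSE
  non[is.na(non)] <- FALSE
  out <- rep("unknown", length(x))
  out[ind & !non] <- "industry"
  out[non & !ind] <- "non_industry"
  factor(out, levels = sponsor_levels())
}

sponsor_levels <- function() c("industry", "non_industry", "unknown")

new_exclusion_report <- function(...) {
  dplyr::bind_rows(tibble::tibble(trial_id = character(), reason = character(),
                                  detail = character()), ...)
}

#' Exclusion report attached to a trial table
#'
#' [read_trials()] and [filter_period()] record every dropped row or location
#' instead of silently discarding it; this accessor retrieves that record.
#'
#' @param x A trial tibble returned by [read_trials()] or [filter_period()].
#' @return A tibble with columns `trial_id`, `reason`, `detail`.
#' @export
exclusion_report <- function(x) {
  rep <- attr(x, "exclusions")
  if (is.null(rep)) new_exclusion_report() else rep
}

#' Read trial records from a registry CSV
#'
#' Expects one row per registered trial with a unique identifier, a start
#' date (any string containing a four-digit year), a primary-sponsor name,
#' and a delimited list of country locations. Country names are resolved to
#' ISO alpha-2 codes and de-duplicated per trial; the sponsor is classified
#' with [classify_sponsor()]. Rows with unparseable start dates or no
#' resolvable country are excluded and recorded in the attached exclusion
#' report (see [exclusion_report()]); an unresolvable name within an
#' otherwise valid country list drops only that location.
#'
#' @param path CSV file path (UTF-8).
#' @param delim Field delimiter, default comma.
#' @param country_delim Delimiter inside the country-list field, default ";".
#' @param columns Named character vector mapping the roles `id`, `start_date`,
#'   `sponsor`, `countries` to the file's column names.
#' @param keywords Sponsor keyword configuration, see [sponsor_keywords()].
#' @param countries Country reference table, see [country_table()].
#' @param extra_aliases Optional alias tibble passed to [resolve_country()].
#' @return A tibble with columns `trial_id`, `start_year`, `sponsor_name`,
#'   `sponsor_type` and the list-column `countries` (character vectors of ISO
#'   codes), with the exclusion report attached as an attribute.
#' @export
read_trials <- function(path, delim = ",", country_delim = ";",
                        columns = c(id = "trial_id", start_date = "start_date",
                                    sponsor = "sponsor", countries = "countries"),
                        keywords = sponsor_keywords(),
                        countries = country_table(),
                        extra_aliases = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, col_types = readr::cols(.default = "c"))
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing) > 0) {
    stop("input file is missing required column(s): ", paste(missing, collapse = ", "))
  }
  tbl <- tibble::tibble(
    trial_id = raw[[columns[["id"]]]],
    start_raw = raw[[columns[["start_date"]]]],
    sponsor_name = raw[[columns[["sponsor"]]]],
    country_raw = raw[[columns[["countries"]]]]
  )

  year <- stringr::str_extract(tbl$start_raw, "\\b(1[89]|2[01])\\d{2}\\b")
  tbl$start_year <- as.integer(year)

  split_raw <- stringr::str_split(dplyr::coalesce(tbl$country_raw, ""),
                                  stringr::fixed(country_delim))
  resolved <- purrr::map(split_raw, function(v) {
    v <- trimws(v)
    v <- v[v != ""]
    codes <- resolve_country(v, countries = countries, extra_aliases = extra_aliases)
    list(codes = sort(unique(codes[!is.na(codes)])), bad = v[is.na(codes)])
  })
  tbl$countries <- purrr::map(resolved, "codes")
  bad_names <- purrr::map(resolved, "bad")

  report <- new_exclusion_report(
    tibble::tibble(
      trial_id = rep(tbl$trial_id, lengths(bad_names)),
      reason = "unresolved_country",
      detail = unlist(bad_names, use.names = FALSE)
    ),
    tibble::tibble(
      trial_id = tbl$trial_id[is.na(tbl$start_year)],
      reason = "unparseable_start_date",
      detail = as.character(tbl$start_raw[is.na(tbl$start_year)])
    ),
    tibble::tibble(
      trial_id = tbl$trial_id[lengths(tbl$countries) == 0],
      reason = "no_resolvable_country",
      detail = as.character(tbl$country_raw[lengths(tbl$countries) == 0])
    )
  )

  keep <- !is.na(tbl$start_year) & lengths(tbl$countries) > 0
  out <- tbl[keep, c("trial_id", "start_year", "sponsor_name", "countries")]
  out$sponsor_type <- classify_sponsor(out$sponsor_name, keywords)
  out <- out[, c("trial_id", "start_year", "sponsor_name", "sponsor_type", "countries")]
  attr(out, "exclusions") <- report
  out
}

#' Write trial records back to CSV
#'
#' Inverse of [read_trials()]: the country set is joined with the chosen
#' delimiter, so a written file re-reads to identical records.
#'
#' @param trials Trial tibble.
#' @param path Output CSV path.
#' @param country_delim Delimiter for the country-list field.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, country_delim = ";") {
  flat <- tibble::tibble(
    trial_id = trials$trial_id,
    start_date = trials$start_year,
    sponsor = trials$sponsor_name,
    countries = purrr::map_chr(trials$countries, paste, collapse = country_delim)
  )
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' Restrict trials to the analysis period and classified sponsors
#'
#' Keeps trials whose start year lies in `[first_year, last_year]` and whose
#' sponsor type is not `unknown`; each exclusion reason is counted separately
#' in the attached report.
#'
#' @param trials Trial tibble.
#' @param first_year,last_year Inclusive year bounds; defaults 2006 and 2013,
#'   the window within which trial registration can be assumed complete.
#' @return Filtered tibble with an exclusion report attribute.
#' @export
filter_period <- function(trials, first_year = 2006, last_year = 2013) {
  in_period <- trials$start_year >= first_year & trials$start_year <= last_year
  known <- trials$sponsor_type != "unknown"
  report <- new_exclusion_report(
    tibble::tibble(trial_id = trials$trial_id[!in_period],
                   reason = "out_of_period",
                   detail = as.character(trials$start_year[!in_period])),
    tibble::tibble(trial_id = trials$trial_id[in_period & !known],
                   reason = "unknown_sponsor",
                   detail = as.character(trials$sponsor_name[in_period & !known]))
  )
  out <- trials[in_period & known, , drop = FALSE]
  attr(out, "exclusions") <- report
  out
}

#' Drop duplicate registrations of the same trial
#'
#' Keeps one record per `trial_id`. When duplicated records disagree, the one
#' with the most country locations wins; remaining ties are broken
#' deterministically (earliest start year, then sponsor fields).
#'
#' @param trials Trial tibble.
#' @return Tibble with unique `trial_id`s, in order of first appearance.
#' @export
deduplicate_trials <- function(trials) {
  trials |>
    dplyr::mutate(.n_countries = lengths(.data$countries),
                  .row = dplyr::row_number()) |>
    dplyr::arrange(dplyr::desc(.data$.n_countries), .data$start_year,
                   .data$sponsor_type, .data$sponsor_name) |>
    dplyr::distinct(.data$trial_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".n_countries", -".row")
}
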