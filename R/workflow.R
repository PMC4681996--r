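#' Run the full collaboration analysis pipeline
#'
#' Orchestrates, for each sponsor type, the chain: period filter and
#' deduplication, descriptive mapping, incidence-matrix construction,
#' trimming, the fixed-margin null model, co-occurrence network assembly,
#' and map-equation clustering. Stage counts, seeds and settings are
#' collected in a run report so a run is fully auditable and reproducible.
#'
#' @param trials Trial tibble (from [read_trials()] or
#'   [generate_registry()]).
#' @param sponsor_types Sponsor networks to analyse.
#' @param trim Named retained-weight fractions per sponsor type; the denser
#'   industry network is conventionally trimmed to 0.95, the non-industry
#'   network to 0.90.
#' @param n_reps Null-model replicates per sponsor network.
#' @param seed Root seed; per-stage seeds are derived from it and recorded.
#' @param n_restarts Restarts of the clustering search.
#' @param countries Country reference table.
#' @param out_dir Optional directory: when given, mapping tables (CSV), null
#'   summaries (CSV), networks (GraphML) and the report (JSON) are written
#'   there.
#' @return An object of class `trial_run_report`: per-sponsor results
#'   (`summaries`, `network`, `partition`, `mapping`) plus `counts` and
#'   `settings`.
#' @export
run_pipeline <- function(trials,
                         sponsor_types = c("industry", "non_industry"),
                         trim = c(industry = 0.95, non_industry = 0.90),
                         n_reps = 90000, seed = 1L, n_restarts = 10L,
                         countries = country_table(), out_dir = NULL) {
  stopifnot(all(trim > 0), all(trim <= 1), n_reps >= 1)
  n_read <- nrow(trials)
  trials <- filter_period(trials)
  excl <- exclusion_report(trials)
  trials <- deduplicate_trials(trials)

  results <- list()
  counts <- list(
    trials_read = n_read,
    excluded_out_of_period = sum(excl$reason == "out_of_period"),
    excluded_unknown_sponsor = sum(excl$reason == "unknown_sponsor"),
    trials_analysed = nrow(trials)
  )
  stage_seed <- function(sponsor, stage) {
    # distinct, recorded sub-seeds derived from the root seed; double
    # arithmetic avoids integer overflow for large root seeds
    as.integer((as.numeric(seed) * 1009 +
                  match(sponsor, sponsor_types) * 101 +
                  match(stage, c("null", "cluster"))) %% (2^31 - 1))
  }

  for (sp in sponsor_types) {
    res <- list()
    res$mapping <- list(
      density = density_table(trials, countries, sponsor = sp),
      international_share = international_share(trials, sp, countries),
      annual = annual_distribution(trials, by = "region", sponsor = sp,
                                   countries = countries)
    )
    m <- build_incidence(trials, sponsor = sp)
    counts[[paste0(sp, "_international_trials")]] <- nrow(m)
    if (nrow(m) == 0 || ncol(m) < 2) {
      res$summaries <- NULL
      res$network <- NULL
      res$partition <- NULL
      counts[[paste0(sp, "_countries")]] <- ncol(m)
      counts[[paste0(sp, "_pairs")]] <- 0L
      counts[[paste0(sp, "_flagged")]] <- 0L
      counts[[paste0(sp, "_clusters")]] <- 0L
      results[[sp]] <- res
      next
    }
    mt <- trim_incidence(m, retain_fraction = unname(trim[sp]))
    counts[[paste0(sp, "_countries")]] <- ncol(mt)
    res$summaries <- null_distributions(mt, n_reps = n_reps,
                                        seed = stage_seed(sp, "null"))
    res$network <- build_cooccurrence_network(res$summaries)
    counts[[paste0(sp, "_pairs")]] <- nrow(res$summaries)
    counts[[paste0(sp, "_flagged")]] <- sum(res$summaries$flagged)
    if (nrow(res$network) > 0) {
      res$partition <- detect_clusters(res$network,
                                       seed = stage_seed(sp, "cluster"),
                                       n_restarts = n_restarts)
      counts[[paste0(sp, "_clusters")]] <- res$partition$n_clusters
    } else {
      res$partition <- NULL
      counts[[paste0(sp, "_clusters")]] <- 0L
    }
    results[[sp]] <- res
  }

  report <- structure(list(
    results = results,
    counts = counts,
    settings = list(sponsor_types = sponsor_types, trim = trim,
                    n_reps = n_reps, seed = seed, n_restarts = n_restarts)
  ), class = "trial_run_report")

  if (!is.null(out_dir)) write_run_outputs(report, out_dir)
  report
}

write_run_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(report$results)) {
    res <- report$results[[sp]]
    readr::write_csv(res$mapping$density,
                     file.path(out_dir, paste0(sp, "_density.csv")), progress = FALSE)
    if (!is.null(res$summaries)) {
      readr::write_csv(res$summaries,
                       file.path(out_dir, paste0(sp, "_summaries.csv")), progress = FALSE)
    }
    if (!is.null(res$network) && nrow(res$network) > 0) {
      write_network(res$network,
                    file.path(out_dir, paste0(sp, "_cooccurrence.graphml")))
    }
    if (!is.null(res$partition)) {
      jsonlite::write_json(
        list(codelength_bits = res$partition$L,
             clusters = split(names(res$partition$membership),
                              res$partition$membership)),
        file.path(out_dir, paste0(sp, "_partition.json")), auto_unbox = TRUE)
    }
  }
  jsonlite::write_json(c(report$counts, report$settings),
                       file.path(out_dir, "report.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' @exportS3Method base::print
print.trial_run_report <- function(x, ...) {
  cat("Trial-registry collaboration analysis\n")
  cat("  trials read:", x$counts$trials_read,
      "| analysed:", x$counts$trials_analysed, "\n")
  for (sp in x$settings$sponsor_types) {
    cat(sprintf("  %s: %d international trials, %d countries after trim, %d/%d pairs flagged, %d clusters\n",
                sp, x$counts[[paste0(sp, "_international_trials")]],
                x$counts[[paste0(sp, "_countries")]],
                x$counts[[paste0(sp, "_flagged")]],
                x$counts[[paste0(sp, "_pairs")]],
                x$counts[[paste0(sp, "_clusters")]]))
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `trial_run_report`.
#' @param ... Unused.
#' @return Tibble with one row per sponsor type and the stage counts.
#' @export
glance.trial_run_report <- function(x, ...) {
  purrr::map_dfr(x$settings$sponsor_types, function(sp) {
    tibble::tibble(
      sponsor_type = sp,
      trials_read = x$counts$trials_read,
      trials_analysed = x$counts$trials_analysed,
      international_trials = x$counts[[paste0(sp, "_international_trials")]],
      countries = x$counts[[paste0(sp, "_countries")]],
      pairs = x$counts[[paste0(sp, "_pairs")]],
      flagged = x$counts[[paste0(sp, "_flagged")]],
      clusters = x$counts[[paste0(sp, "_clusters")]]
    )
  })
}

#' Tidy the flagged collaborations of a pipeline run
#'
#' @param x A `trial_run_report`.
#' @param ... Unused.
#' @return Tibble of per-pair null summaries for all sponsor types, with a
#'   `sponsor_type` column and the overrepresentation degree.
#' @export
tidy.trial_run_report <- function(x, ...) {
  purrr::map_dfr(names(x$results), function(sp) {
    sm <- x$results[[sp]]$summaries
    if (is.null(sm)) return(NULL)
    dplyr::mutate(sm, sponsor_type = sp,
                  degree = overrep_degree(.data$observed, .data$null_mean,
                                          .data$null_q999),
                  .before = 1)
  })
}
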