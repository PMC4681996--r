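#' Fixed-margin randomization of an incidence matrix
#'
#' Draws a binary matrix with exactly the row and column sums of the input,
#' approximately uniformly over all such matrices (the "fill class"), by
#' repeated curveball trades: two rows are picked at random and exchange a
#' random subset of the columns they do not share, which leaves both margins
#' untouched.
#'
#' @param m Binary incidence matrix (see [build_incidence()]).
#' @param n_steps Number of trades; the default of five trades per row is a
#'   conservative mixing allowance for sparse trial matrices.
#' @param seed Optional integer seed for reproducibility.
#' @return A sparse binary matrix with the same dimensions, dimnames and
#'   margins as `m`.
#' @export
randomize_fixed_margins <- function(m, n_steps = 5 * nrow(m), seed = NULL) {
  check_incidence(m)
  if (!is.null(seed)) set.seed(seed)
  if (nrow(m) < 2 || ncol(m) < 2) return(m)
  rs <- cpp_curveball(incidence_rowsets(m), ncol(m), as.integer(n_steps))
  rowsets_to_matrix(rs, dim(m), dimnames(m))
}

pair_table <- function(codes) {
  n <- length(codes)
  if (n < 2) {
    return(tibble::tibble(country_a = character(), country_b = character()))
  }
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n), use.names = FALSE)
  tibble::tibble(country_a = codes[i], country_b = codes[j])
}

#' Empirical percentile as an order statistic
#'
#' Returns the `ceiling(p * n)`-th order statistic of the sample, without
#' interpolation, so that at least a fraction `p` of the sample lies at or
#' below the returned value.
#'
#' @param x Numeric sample.
#' @param p Percentile level in (0, 1].
#' @return A single number.
#' @export
#' @examples
#' empirical_percentile(1:1000, 0.999) # 999
empirical_percentile <- function(x, p = 0.999) {
  stopifnot(length(x) >= 1, p > 0, p <= 1)
  sort(x)[ceiling(p * length(x))]
}

#' @rdname empirical_percentile
#' @export
empirical_q999 <- function(x) empirical_percentile(x, 0.999)

#' Per-pair null distributions of country co-occurrence
#'
#' Generates `n_reps` fixed-margin randomizations of the incidence matrix
#' and summarizes, for every unordered country pair, the null distribution
#' of their co-occurrence: its mean and its empirical 99.9th percentile (the
#' `ceiling(0.999 n)` order statistic). A pair is flagged as overrepresented
#' when its observed co-occurrence strictly exceeds that percentile, a
#' deliberately conservative rule under which percentile ties are not
#' flagged. Distributions are accumulated as bounded integer histograms
#' (co-occurrence cannot exceed the smaller column margin), so memory stays
#' modest even at 90,000 replicates.
#'
#' Two sampling modes are available: `"chain"` (default) continues one long
#' Markov chain, taking one sample per full sweep of trades after a burn-in;
#' `"independent"` restarts from the observed matrix for every replicate.
#' The chain mode is much faster at large `n_reps`; the independent mode is
#' useful for uniformity diagnostics.
#'
#' @param m Incidence matrix, normally after [trim_incidence()].
#' @param n_reps Number of null replicates; 90,000 makes the 99.9th
#'   percentile stable to about +/- 0.01 percentage points of coverage.
#' @param seed Optional integer seed.
#' @param mode `"chain"` or `"independent"`.
#' @param burnin Trades discarded before the first chain sample (default
#'   five per row).
#' @param thin Trades between chain samples (default one per row, a full
#'   sweep).
#' @param n_steps_indep Trades per replicate in independent mode.
#' @return Tibble with one row per country pair: `country_a`, `country_b`,
#'   `observed`, `null_mean`, `null_q999`, `n_reps`, `flagged`.
#' @export
null_distributions <- function(m, n_reps = 90000, seed = NULL,
                               mode = c("chain", "independent"),
                               burnin = 5 * nrow(m), thin = max(1, nrow(m)),
                               n_steps_indep = 5 * nrow(m)) {
  mode <- match.arg(mode)
  check_incidence(m)
  if (n_reps < 1000) {
    warning("fewer than 1,000 replicates: the 99.9th percentile is unstable")
  }
  if (!is.null(seed)) set.seed(seed)
  codes <- colnames(m)
  pairs <- pair_table(codes)
  if (nrow(pairs) == 0 || nrow(m) == 0) {
    return(dplyr::mutate(pairs, observed = integer(), null_mean = numeric(),
                         null_q999 = numeric(), n_reps = integer(),
                         flagged = logical()))
  }
  rs <- incidence_rowsets(m)
  observed <- cpp_cooccurrence_counts(rs, ncol(m))
  hist <- cpp_null_histograms(rs, ncol(m), as.integer(n_reps),
                              as.integer(burnin), as.integer(thin),
                              ifelse(mode == "chain", 0L, 1L),
                              as.integer(n_steps_indep))
  values <- seq_len(ncol(hist)) - 1
  null_mean <- as.numeric(hist %*% values) / n_reps
  k <- ceiling(0.999 * n_reps)
  cum <- t(apply(hist, 1, cumsum))
  null_q999 <- as.numeric(apply(cum < k, 1, sum)) # first value with cum >= k
  pairs |>
    dplyr::mutate(
      observed = as.integer(observed),
      null_mean = null_mean,
      null_q999 = null_q999,
      n_reps = as.integer(n_reps),
      flagged = .data$observed > .data$null_q999
    )
}

#' Type-I calibration of the percentile test against held-out null draws
#'
#' Estimates the realized false-positive rate of the overrepresentation
#' test: per-pair 99.9th-percentile thresholds are taken from `summaries`
#' (or computed with [null_distributions()]), then `n_draws` further
#' fixed-margin replicates are generated and each replicate's co-occurrence
#' is compared per pair against the threshold. Because the held-out
#' replicates come from the null itself, the exceedance fraction estimates
#' the test's actual size, nominally 0.1% (discreteness of the integer
#' co-occurrence counts makes the realized size somewhat conservative).
#'
#' @param m Incidence matrix (trimmed).
#' @param summaries Optional precomputed output of [null_distributions()]
#'   for `m`; computed at `n_reps` replicates when omitted.
#' @param n_reps Replicates used for the thresholds when `summaries` is
#'   missing.
#' @param n_draws Held-out null replicates to test against the thresholds.
#' @param seed Integer seed for the held-out chain.
#' @return A list with `rate` (overall exceedance fraction), `n_pair_tests`
#'   (`pairs x draws`), `n_pairs` and `n_draws`.
#' @export
null_calibration <- function(m, summaries = NULL, n_reps = 5000,
                             n_draws = 200, seed = NULL) {
  check_incidence(m)
  if (is.null(summaries)) {
    summaries <- null_distributions(m, n_reps = n_reps, seed = seed)
  }
  if (!is.null(seed)) set.seed(seed + 1L)
  rs <- incidence_rowsets(m)
  exceed <- cpp_null_exceedances(rs, ncol(m), as.integer(n_draws),
                                 as.integer(5 * nrow(m)),
                                 as.integer(max(1, nrow(m))),
                                 summaries$null_q999)
  list(rate = sum(exceed) / (nrow(summaries) * n_draws),
       n_pair_tests = nrow(summaries) * n_draws,
       n_pairs = nrow(summaries), n_draws = n_draws)
}

#' Degree of overrepresentation of a collaboration
#'
#' The distance of the observed co-occurrence above the null mean, expressed
#' in units of the distance between the null 99.9th percentile and the null
#' mean: `D = (observed - null_mean) / (null_q999 - null_mean)`. `D` equals
#' 0 at the null mean and 1 exactly at the percentile; flagged pairs have
#' `D > 1`. When the percentile does not exceed the mean the degree is
#' undefined and `NA` is returned.
#'
#' @param observed Observed co-occurrence count(s).
#' @param null_mean Null-distribution mean(s).
#' @param null_q999 Null 99.9th percentile(s).
#' @return Numeric vector of degrees, `NA` where degenerate.
#' @export
#' @examples
#' overrep_degree(10, 4, 8) # 1.5
overrep_degree <- function(observed, null_mean, null_q999) {
  ifelse(null_q999 > null_mean,
         (observed - null_mean) / (null_q999 - null_mean),
         NA_real_)
}

#' Co-occurrence network of overrepresented collaborations
#'
#' Builds the network whose edges are the flagged (overrepresented) country
#' pairs, weighted by their degree of overrepresentation. Flagged pairs with
#' a degenerate null (percentile equal to the mean) cannot carry a degree
#' and are reported separately in the `"degenerate"` attribute.
#'
#' @param summaries Output of [null_distributions()].
#' @param include_isolated If `TRUE`, countries without any flagged edge are
#'   kept as isolated nodes of the network.
#' @return Edge tibble `country_a`, `country_b`, `degree` with attributes
#'   `"nodes"` (character vector) and `"degenerate"` (tibble of flagged
#'   pairs without a degree).
#' @export
build_cooccurrence_network <- function(summaries, include_isolated = FALSE) {
  sm <- dplyr::mutate(summaries,
                      degree = overrep_degree(.data$observed, .data$null_mean,
                                              .data$null_q999))
  edges <- sm |>
    dplyr::filter(.data$flagged, !is.na(.data$degree)) |>
    dplyr::select("country_a", "country_b", "degree")
  degenerate <- sm |>
    dplyr::filter(.data$flagged, is.na(.data$degree)) |>
    dplyr::select("country_a", "country_b", "observed", "null_mean", "null_q999")
  nodes <- sort(unique(c(edges$country_a, edges$country_b)))
  if (include_isolated) {
    nodes <- sort(unique(c(nodes, summaries$country_a, summaries$country_b)))
  }
  attr(edges, "nodes") <- nodes
  attr(edges, "degenerate") <- degenerate
  edges
}
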