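#' Configuration for the synthetic registry generator
#'
#' The generator emulates the statistical structure of an international
#' trial registry over 2006-2013: per-country trial volumes proportional to
#' population with income-group-specific base densities, an industry/
#' non-industry sponsor mix that varies by income group, a per-sponsor
#' probability that a trial is international, a countries-per-international-
#' trial distribution, and optional planted "blocks" of countries that
#' co-participate more than size alone would predict.
#'
#' Defaults reflect typical registry conditions: median densities of 116,
#' 13.8, 1.8 and 1.1 trials per million across the four income groups;
#' industry shares of 51.6%, 66.0%, 65.4% and 9.3%; international
#' probabilities of 30.3% (industry) and 3.2% (non-industry); and a shifted
#' geometric countries-per-trial distribution `k = 2 + Geometric(prob)`
#' whose success probabilities 0.55 and 0.18 put the medians at 2 (industry)
#' and 5 (non-industry) countries.
#'
#' @param countries Country reference table, see [country_table()].
#' @param base_rate Named numeric: expected trials per million inhabitants
#'   over the whole period, by income group.
#' @param industry_fraction Named numeric: probability a trial is
#'   industry-sponsored, by income group.
#' @param p_international Named numeric: probability a trial is
#'   international, by sponsor type.
#' @param k_geom_prob Named numeric: success probability of the shifted
#'   geometric distribution of countries per international trial, by sponsor
#'   type.
#' @param blocks List of planted blocks, each a list with `members`
#'   (character vector of ISO codes) and `affinity` (multiplier >= 1 on the
#'   partner-selection weight between block members).
#' @param years Integer vector of admissible start years.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    countries = country_table(),
    base_rate = c(high = 116, upper_middle = 13.8, lower_middle = 1.8, low = 1.1),
    industry_fraction = c(high = 0.516, upper_middle = 0.660,
                          lower_middle = 0.654, low = 0.093),
    p_international = c(industry = 0.303, non_industry = 0.032),
    k_geom_prob = c(industry = 0.55, non_industry = 0.18),
    blocks = list(),
    years = 2006:2013) {
  if (nrow(countries) == 0) stop("config needs at least one country")
  stopifnot(all(income_group_levels() %in% names(base_rate)),
            all(income_group_levels() %in% names(industry_fraction)),
            all(c("industry", "non_industry") %in% names(p_international)),
            all(c("industry", "non_industry") %in% names(k_geom_prob)))
  stopifnot(all(industry_fraction >= 0 & industry_fraction <= 1),
            all(p_international >= 0 & p_international <= 1),
            all(k_geom_prob > 0 & k_geom_prob <= 1),
            all(base_rate >= 0))
  for (b in blocks) {
    stopifnot(is.character(b$members), length(b$members) >= 2,
              all(b$members %in% countries$code),
              is.numeric(b$affinity), b$affinity >= 1)
  }
  structure(list(countries = countries, base_rate = base_rate,
                 industry_fraction = industry_fraction,
                 p_international = p_international,
                 k_geom_prob = k_geom_prob, blocks = blocks, years = years),
            class = "synthetic_config")
}

block_affinity_matrix <- function(config) {
  codes <- config$countries$code
  aff <- matrix(1, length(codes), length(codes), dimnames = list(codes, codes))
  for (b in config$blocks) {
    aff[b$members, b$members] <- pmax(aff[b$members, b$members], b$affinity)
  }
  diag(aff) <- 0
  aff
}

#' Generate a synthetic trial registry
#'
#' Draws a registry of trial records under a [synthetic_config()]: each
#' country anchors a Poisson number of trials with mean
#' `base_rate[income] * population / 1e6`; each trial gets a sponsor type
#' (income-group industry fraction), a uniform start year, and is
#' international with the sponsor-specific probability. An international
#' trial draws its total country count `k` from the sponsor's shifted
#' geometric distribution (capped at the number of available countries) and
#' picks its `k - 1` partner countries without replacement with probability
#' proportional to a partner size weight — the square root of population in
#' millions, since participation breadth grows subproportionally with
#' country size — times the block affinity multiplier when anchor and
#' partner share a planted block.
#'
#' @param config A `synthetic_config`.
#' @param seed Integer seed; the same seed reproduces the registry exactly.
#' @param rate_scale Global multiplier on `base_rate`, convenient for
#'   generating reduced-size registries without touching the per-income
#'   rates.
#' @return A trial tibble with the same columns as [read_trials()] output.
#' @export
generate_registry <- function(config, seed = 1L, rate_scale = 1) {
  stopifnot(inherits(config, "synthetic_config"), rate_scale >= 0)
  set.seed(seed)
  ct <- config$countries
  pop_m <- ct$population_2012 / 1e6
  mean_trials <- rate_scale * config$base_rate[as.character(ct$income_group)] * pop_m
  n_per_country <- stats::rpois(nrow(ct), mean_trials)
  n_total <- sum(n_per_country)
  if (n_total == 0) {
    return(tibble::tibble(trial_id = character(), start_year = integer(),
                          sponsor_name = character(),
                          sponsor_type = factor(character(), levels = sponsor_levels()),
                          countries = list()))
  }
  anchor_idx <- rep(seq_len(nrow(ct)), n_per_country)
  p_ind <- config$industry_fraction[as.character(ct$income_group)][anchor_idx]
  sponsor <- ifelse(stats::runif(n_total) < p_ind, "industry", "non_industry")
  year <- sample(config$years, n_total, replace = TRUE)
  intl <- stats::runif(n_total) < config$p_international[sponsor]
  k <- rep(1L, n_total)
  k[intl] <- 2L + stats::rgeom(sum(intl), config$k_geom_prob[sponsor[intl]])
  k <- pmin(k, nrow(ct))

  aff <- block_affinity_matrix(config)
  base_w <- sqrt(pop_m)
  countries <- vector("list", n_total)
  codes <- ct$code
  for (t in seq_len(n_total)) {
    a <- anchor_idx[t]
    if (k[t] == 1L) {
      countries[[t]] <- codes[a]
    } else {
      w <- base_w * aff[a, ]
      partners <- sample(seq_len(nrow(ct)), k[t] - 1L, prob = w)
      countries[[t]] <- sort(codes[c(a, partners)])
    }
  }
  tibble::tibble(
    trial_id = sprintf("SYN%06d", seq_len(n_total)),
    start_year = as.integer(year),
    sponsor_name = NA_character_,
    sponsor_type = factor(sponsor, levels = sponsor_levels()),
    countries = countries
  )
}

#' Enumerate the fill class of a small binary matrix
#'
#' Lists every binary matrix sharing the row and column sums of `m`, by
#' backtracking over rows. Intended for test oracles on tiny fixtures; the
#' enumeration aborts once `max_size` matrices have been found.
#'
#' @param m A small binary matrix (dense or sparse).
#' @param max_size Cap on the class size.
#' @return List of binary base-R matrices; `m`'s own pattern is among them.
#' @export
enumerate_fill_class <- function(m, max_size = 100000) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  rs <- rowSums(m)
  cs <- colSums(m)
  n <- nrow(m); p <- ncol(m)
  out <- list()
  subsets <- function(cols, k) {
    if (k == 0) return(list(integer()))
    if (length(cols) < k) return(list())
    utils::combn(cols, k, simplify = FALSE)
  }
  recurse <- function(row, remaining_cs, acc) {
    if (length(out) >= max_size) stop("fill class larger than max_size")
    if (row > n) {
      if (all(remaining_cs == 0)) out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    # feasibility: no column may need more rows than remain
    if (any(remaining_cs > n - row + 1)) return(invisible())
    for (s in subsets(which(remaining_cs > 0), rs[row])) {
      acc[row, ] <- 0L
      acc[row, s] <- 1L
      ncs <- remaining_cs
      ncs[s] <- ncs[s] - 1L
      recurse(row + 1, ncs, acc)
    }
    invisible()
  }
  recurse(1, cs, matrix(0L, n, p, dimnames = dimnames(m)))
  out
}

#' Small incidence fixture together with its enumerated fill class
#'
#' Convenience for oracle tests: builds a tiny binary matrix with the given
#' margins-by-example and returns both the matrix and every binary matrix
#' sharing its margins.
#'
#' @param m Binary matrix to use as the fixture (default: the 3x3 matrix
#'   with all row and column sums 2, whose fill class has 6 members).
#' @param max_size Cap passed to [enumerate_fill_class()].
#' @return List with elements `matrix` and `fill_class`.
#' @export
generate_fill_class_fixture <- function(m = NULL, max_size = 100000) {
  if (is.null(m)) {
    m <- matrix(c(1, 1, 0,
                  0, 1, 1,
                  1, 0, 1), nrow = 3, byrow = TRUE,
                dimnames = list(paste0("t", 1:3), c("AA", "BB", "CC")))
  }
  list(matrix = Matrix::Matrix(m, sparse = TRUE),
       fill_class = enumerate_fill_class(m, max_size))
}
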