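#' Build the trial-by-country incidence matrix
#'
#' Rows are international trials (at least two countries) of the requested
#' sponsor type, columns are ISO country codes, and cells are binary
#' participation indicators. The row margins are countries-per-trial
#' (all >= 2) and the column margins are international-trials-per-country;
#' this matrix is what the fixed-margin null model permutes.
#'
#' @param trials Filtered, deduplicated trial tibble.
#' @param sponsor Optional sponsor type restriction.
#' @return A sparse binary `Matrix` (class `dgCMatrix`) with trial ids as
#'   row names and sorted ISO codes as column names. Zero international
#'   trials yield a 0-row matrix.
#' @export
build_incidence <- function(trials, sponsor = NULL) {
  sub <- restrict_trials(trials, sponsor, international = TRUE)
  codes <- sort(unique(unlist(sub$countries, use.names = FALSE)))
  if (nrow(sub) == 0) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(0L, 0L),
                                dimnames = list(character(), character())))
  }
  i <- rep(seq_len(nrow(sub)), lengths(sub$countries))
  j <- match(unlist(sub$countries, use.names = FALSE), codes)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(nrow(sub), length(codes)),
                       dimnames = list(sub$trial_id, codes))
}

check_incidence <- function(m) {
  stopifnot(inherits(m, "Matrix") || is.matrix(m))
  if (nrow(m) > 0 && any(Matrix::rowSums(m) < 2)) {
    stop("incidence matrix has rows with fewer than 2 countries")
  }
  invisible(m)
}

# 0-based column-index sets per row, the representation the C++ code uses
incidence_rowsets <- function(m) {
  m <- methods::as(methods::as(m, "CsparseMatrix"), "TsparseMatrix")
  split(m@j, factor(m@i, levels = seq_len(nrow(m)) - 1L))
}

rowsets_to_matrix <- function(rowsets, dims, dimnames) {
  i <- rep(seq_along(rowsets), lengths(rowsets))
  j <- unlist(rowsets, use.names = FALSE) + 1L
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = dims, dimnames = dimnames)
}

#' Country-country collaboration weights
#'
#' The collaboration (co-occurrence) weight of a country pair is the number
#' of trials in which both countries appear, counted once per trial no
#' matter how many further countries the trial includes.
#'
#' @param m Incidence matrix from [build_incidence()].
#' @return Tibble of undirected edges: `country_a` < `country_b`, `weight`,
#'   with zero-weight pairs omitted.
#' @export
cooccurrence <- function(m) {
  check_incidence(m)
  if (nrow(m) == 0 || ncol(m) < 2) {
    return(tibble::tibble(country_a = character(), country_b = character(),
                          weight = integer()))
  }
  cp <- as.matrix(Matrix::crossprod(m))
  idx <- which(upper.tri(cp) & cp > 0, arr.ind = TRUE)
  tibble::tibble(
    country_a = colnames(m)[idx[, 1]],
    country_b = colnames(m)[idx[, 2]],
    weight = as.integer(cp[idx])
  ) |>
    dplyr::arrange(.data$country_a, .data$country_b)
}

total_collaboration_weight <- function(m) {
  k <- Matrix::rowSums(m)
  sum(k * (k - 1) / 2)
}

#' Trim sparsely collaborating countries from the incidence matrix
#'
#' Removes countries one at a time — always the country currently
#' participating in the fewest international trials, ties broken
#' alphabetically — re-evaluating the margins after each removal. A removal
#' is only carried out if the retained total pairwise collaboration weight
#' stays at or above `retain_fraction` of the original total. Trials left
#' with fewer than two countries are dropped, and countries that end with no
#' trials are dropped with them.
#'
#' @param m Incidence matrix.
#' @param retain_fraction Fraction of total collaboration weight to retain;
#'   the conventional values are 0.95 for the denser industry network and
#'   0.90 for the non-industry network.
#' @return Trimmed incidence matrix; the removed country codes are attached
#'   as attribute `"removed"` and the pre-trim total weight as
#'   `"trim_total0"`. A previously trimmed matrix keeps its original
#'   reference total, so trimming is idempotent.
#' @export
trim_incidence <- function(m, retain_fraction = 0.95) {
  stopifnot(retain_fraction > 0, retain_fraction <= 1)
  check_incidence(m)
  total0 <- attr(m, "trim_total0")
  if (is.null(total0)) total0 <- total_collaboration_weight(m)
  removed <- character()
  if (total0 == 0) {
    attr(m, "removed") <- removed
    attr(m, "trim_total0") <- total0
    return(m)
  }
  repeat {
    if (ncol(m) <= 2) break
    cs <- Matrix::colSums(m)
    ord <- order(cs, colnames(m))
    victim <- colnames(m)[ord[1]]
    cand <- drop_country(m, victim)
    if (total_collaboration_weight(cand) < retain_fraction * total0) break
    removed <- c(removed, victim)
    m <- cand
  }
  # countries that lost all their trials carry no collaborations
  empty <- Matrix::colSums(m) == 0
  if (any(empty)) {
    removed <- c(removed, colnames(m)[empty])
    m <- m[, !empty, drop = FALSE]
  }
  attr(m, "removed") <- removed
  attr(m, "trim_total0") <- total0
  m
}

drop_country <- function(m, code) {
  m <- m[, colnames(m) != code, drop = FALSE]
  m[Matrix::rowSums(m) >= 2, , drop = FALSE]
}

#' Convert an edge tibble to an igraph graph
#'
#' @param edges Tibble with columns `country_a`, `country_b` and a weight
#'   column (`weight` or `degree`).
#' @param nodes Optional character vector of node names to include even if
#'   isolated.
#' @return An undirected weighted `igraph` graph.
#' @export
as_collab_graph <- function(edges, nodes = NULL) {
  wcol <- intersect(c("weight", "degree"), names(edges))[1]
  el <- data.frame(from = edges$country_a, to = edges$country_b,
                   weight = edges[[wcol]])
  vs <- sort(unique(c(nodes, el$from, el$to)))
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = vs)
}

#' Export a network as GraphML or a weighted edge-list TSV
#'
#' @param edges Edge tibble (see [cooccurrence()] or
#'   [build_cooccurrence_network()]).
#' @param path Output file path.
#' @param format `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_collab_graph(edges), path, format = "graphml")
  } else {
    wcol <- intersect(c("weight", "degree"), names(edges))[1]
    readr::write_tsv(
      tibble::tibble(source = edges$country_a, target = edges$country_b,
                     weight = edges[[wcol]]),
      path, progress = FALSE)
  }
  invisible(path)
}
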