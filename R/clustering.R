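#' Stationary visit rates of the collaboration flow
#'
#' For an undirected weighted network, the stationary distribution of a
#' random walk visits each node proportionally to its strength (sum of
#' incident edge weights); no teleportation is used. These visit rates are
#' the flow volumes that the map equation encodes.
#'
#' @param edges Edge tibble with columns `country_a`/`country_b` (or
#'   `from`/`to`) and a positive weight column (`weight` or `degree`).
#' @return An object of class `flow_network`: a list with `nodes` (tibble
#'   `node`, `strength`, `p`), `edges` (tibble `from`, `to`, `weight`) and
#'   `total_weight`.
#' @export
visit_rates <- function(edges) {
  e <- normalize_edges(edges)
  if (nrow(e) == 0) stop("cannot compute visit rates of an empty network")
  stopifnot(all(e$weight > 0))
  strength <- tapply(c(e$weight, e$weight), c(e$from, e$to), sum)
  nodes <- tibble::tibble(node = names(strength),
                          strength = as.numeric(strength))
  nodes$p <- nodes$strength / sum(nodes$strength)
  e$from_idx <- match(e$from, nodes$node)
  e$to_idx <- match(e$to, nodes$node)
  structure(list(nodes = nodes, edges = e, total_weight = sum(e$weight)),
            class = "flow_network")
}

normalize_edges <- function(edges) {
  if (all(c("country_a", "country_b") %in% names(edges))) {
    from <- edges$country_a; to <- edges$country_b
  } else {
    from <- edges$from; to <- edges$to
  }
  wcol <- intersect(c("weight", "degree"), names(edges))[1]
  tibble::tibble(from = as.character(from), to = as.character(to),
                 weight = as.numeric(edges[[wcol]])) |>
    dplyr::filter(.data$from != .data$to)
}

plogp <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

# Core two-level map-equation evaluation. p: visit rates; w: edge weights
# already divided by 2 * total weight; mfrom/mto: module of each endpoint.
map_L <- function(p, w, mfrom, mto, mod) {
  mod <- as.integer(factor(mod))
  nmod <- max(mod)
  mf <- mod[mfrom]
  mt <- mod[mto]
  cross <- mf != mt
  q <- numeric(nmod)
  if (any(cross)) {
    agg <- rowsum(rep(w[cross], 2L), c(mf[cross], mt[cross]))
    q[as.integer(rownames(agg))] <- agg[, 1]
  }
  p_mod <- numeric(nmod)
  aggp <- rowsum(p, mod)
  p_mod[as.integer(rownames(aggp))] <- aggp[, 1]
  L <- plogp(sum(q)) - 2 * sum(plogp(q)) - sum(plogp(p)) + sum(plogp(q + p_mod))
  max(L, 0)
}

#' Two-level map equation of a partition
#'
#' The expected description length, in bits per step, of a random walk on
#' the network encoded with a two-level codebook structure: one index
#' codebook for entering modules and one codebook per module for
#' within-module visits and exits. Partitions that trap the flow inside
#' modules — much collaboration within, little between — yield shorter
#' descriptions, so community detection minimizes this quantity.
#'
#' With all nodes in one module the exit terms vanish and the value reduces
#' to the entropy of the visit rates.
#'
#' @param flow A `flow_network` from [visit_rates()] (an edge tibble is also
#'   accepted and converted).
#' @param membership Module assignment: a vector of cluster ids named by
#'   node, or unnamed in the order of `flow$nodes$node`.
#' @return The map-equation value in bits (non-negative scalar).
#' @export
map_equation <- function(flow, membership) {
  if (!inherits(flow, "flow_network")) flow <- visit_rates(flow)
  nodes <- flow$nodes
  if (!is.null(names(membership))) {
    membership <- membership[nodes$node]
    if (anyNA(membership)) stop("membership misses some nodes")
  }
  stopifnot(length(membership) == nrow(nodes))
  map_L(nodes$p, flow$edges$weight / (2 * flow$total_weight),
        flow$edges$from_idx, flow$edges$to_idx, membership)
}

#' Flow-based community detection by map-equation minimization
#'
#' Partitions the network into clusters minimizing the two-level
#' [map_equation()]: a greedy agglomerative phase merges the pair of
#' connected clusters whose merger most decreases the description length,
#' followed by node-level refinement sweeps that move single nodes between
#' neighbouring clusters (or into a fresh singleton) while any move helps.
#' The search is repeated from `n_restarts` random sweep orders and the best
#' partition is kept. Merge ties are broken toward the pair with the
#' smallest member nodes in sort order, so runs are deterministic given the
#' seed. Disconnected components are clustered independently and never
#' merged.
#'
#' @param edges Edge tibble (e.g. from [build_cooccurrence_network()] or
#'   [cooccurrence()]).
#' @param seed Integer seed making the search deterministic.
#' @param n_restarts Number of restarts; the small networks this package
#'   targets rarely need more than 10.
#' @return An object of class `trial_partition`: list with `membership`
#'   (named integer vector, contiguous cluster ids), `L` (bits),
#'   `n_clusters`, and the `flow_network`.
#' @export
detect_clusters <- function(edges, seed = 1L, n_restarts = 10L) {
  flow <- if (inherits(edges, "flow_network")) edges else visit_rates(edges)
  set.seed(seed)
  nodes <- flow$nodes$node
  n <- length(nodes)
  g <- igraph::graph_from_data_frame(flow$edges[, c("from", "to", "weight")],
                                     directed = FALSE, vertices = nodes)
  comp <- as.integer(igraph::components(g)$membership[nodes])

  p <- flow$nodes$p
  w <- flow$edges$weight / (2 * flow$total_weight)
  ef <- flow$edges$from_idx
  et <- flow$edges$to_idx
  nbrs <- lapply(seq_len(n), function(i) c(et[ef == i], ef[et == i]))

  best <- NULL
  for (r in seq_len(n_restarts)) {
    mem <- greedy_search(p, w, ef, et, comp, nbrs, sample.int(n))
    L <- map_L(p, w, ef, et, mem)
    if (is.null(best) || L < best$L - 1e-12) best <- list(mem = mem, L = L)
  }
  mem <- as.integer(factor(best$mem, levels = unique(best$mem)))
  names(mem) <- nodes
  structure(list(membership = mem, L = best$L,
                 n_clusters = max(mem), flow = flow),
            class = "trial_partition")
}

greedy_search <- function(p, w, ef, et, comp, nbrs, sweep_order) {
  n <- length(p)
  mem <- seq_len(n)
  repeat {
    improved <- FALSE
    # agglomerative phase: merge the connected cluster pair that most
    # decreases the description length, until no merge helps
    repeat {
      L0 <- map_L(p, w, ef, et, mem)
      a <- pmin(mem[ef], mem[et])
      b <- pmax(mem[ef], mem[et])
      keep <- a != b & comp[match(a, mem)] == comp[match(b, mem)]
      cand <- unique(cbind(a[keep], b[keep]))
      if (is.null(dim(cand)) || nrow(cand) == 0) break
      cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
      best_d <- 1e-12; best_pair <- NULL
      for (k in seq_len(nrow(cand))) {
        trial <- mem
        trial[trial == cand[k, 2]] <- cand[k, 1]
        d <- L0 - map_L(p, w, ef, et, trial)
        if (d > best_d) { best_d <- d; best_pair <- cand[k, ] }
      }
      if (is.null(best_pair)) break
      mem[mem == best_pair[2]] <- best_pair[1]
      improved <- TRUE
    }
    # refinement phase: single-node moves to neighbouring clusters
    moved <- TRUE
    while (moved) {
      moved <- FALSE
      for (i in sweep_order) {
        targets <- setdiff(unique(c(mem[nbrs[[i]]], max(mem) + 1L)), mem[i])
        if (length(targets) == 0) next
        L0 <- map_L(p, w, ef, et, mem)
        best_d <- 1e-12; best_t <- NA_integer_
        for (t in targets) {
          trial <- mem
          trial[i] <- t
          d <- L0 - map_L(p, w, ef, et, trial)
          if (d > best_d) { best_d <- d; best_t <- t }
        }
        if (!is.na(best_t)) {
          mem[i] <- best_t
          moved <- TRUE
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  mem
}

#' @exportS3Method base::print
print.trial_partition <- function(x, ...) {
  cat("Map-equation partition:", x$n_clusters, "cluster(s),",
      format(x$L, digits = 6), "bits over", length(x$membership), "nodes\n")
  invisible(x)
}

#' Tidy a map-equation partition
#'
#' @param x A `trial_partition`.
#' @param ... Unused.
#' @return Tibble with columns `node` and `cluster`.
#' @export
tidy.trial_partition <- function(x, ...) {
  tibble::tibble(node = names(x$membership),
                 cluster = as.integer(x$membership))
}

#' One-row summary of a map-equation partition
#'
#' @param x A `trial_partition`.
#' @param ... Unused.
#' @return Tibble with `n_nodes`, `n_clusters`, `codelength_bits`.
#' @export
glance.trial_partition <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$membership),
                 n_clusters = x$n_clusters,
                 codelength_bits = x$L)
}

#' Write a partition as a Pajek .clu file
#'
#' @param partition A `trial_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clu <- function(partition, path) {
  writeLines(c(sprintf("*Vertices %d", length(partition$membership)),
               as.character(partition$membership)), path)
  invisible(path)
}
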