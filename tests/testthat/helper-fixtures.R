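# Shared fixtures and independent oracles used across test files.

# Construct a trial tibble directly, bypassing CSV parsing.
make_trials <- function(ids, years, sponsors, country_sets, names = NA_character_) {
  tibble::tibble(
    trial_id = ids,
    start_year = as.integer(years),
    sponsor_name = rep_len(names, length(ids)),
    sponsor_type = factor(sponsors,
                          levels = c("industry", "non_industry", "unknown")),
    countries = lapply(country_sets, sort)
  )
}

# Small binary matrix helper with trial/country dimnames.
make_incidence <- function(rows, codes) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(paste0("t", seq_along(rows)), codes)
  Matrix::Matrix(m, sparse = TRUE)
}

# Brute-force pairwise co-occurrence by a double loop over trials —
# independent of the crossprod-based implementation.
brute_cooccurrence <- function(country_sets) {
  codes <- sort(unique(unlist(country_sets)))
  out <- list()
  for (a_i in seq_along(codes)) {
    for (b_i in seq_along(codes)) {
      if (b_i <= a_i) next
      w <- sum(vapply(country_sets, function(s) {
        codes[a_i] %in% s && codes[b_i] %in% s
      }, logical(1)))
      if (w > 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          country_a = codes[a_i], country_b = codes[b_i], weight = as.integer(w))
      }
    }
  }
  dplyr::bind_rows(out)
}

# Enumerate all set partitions of 1..n (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxblock) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(maxblock + 1)) {
      recurse(c(prefix, b), max(maxblock, b))
    }
    invisible()
  }
  recurse(integer(), 0L)
  out
}

# Term-by-term map-equation oracle, written independently of map_L():
# explicit entropies of the index codebook and each module codebook.
oracle_map_equation <- function(edges, membership) {
  e <- edges
  nodes <- sort(unique(c(e$country_a, e$country_b)))
  stopifnot(length(membership) == length(nodes))
  names(membership) <- nodes
  W <- sum(e$weight)
  strength <- sapply(nodes, function(v) {
    sum(e$weight[e$country_a == v]) + sum(e$weight[e$country_b == v])
  })
  p <- strength / (2 * W)
  mods <- unique(membership)
  entropy <- function(probs) {
    probs <- probs[probs > 0]
    -sum(probs * log2(probs))
  }
  q_m <- sapply(mods, function(m) {
    cross <- xor(membership[e$country_a] == m, membership[e$country_b] == m)
    sum(e$weight[cross]) / (2 * W)
  })
  q <- sum(q_m)
  index_term <- if (q > 0) q * entropy(q_m / q) else 0
  module_terms <- sapply(seq_along(mods), function(k) {
    m <- mods[k]
    pm <- p[membership == m]
    tot <- q_m[k] + sum(pm)
    tot * entropy(c(q_m[k], pm) / tot)
  })
  index_term + sum(module_terms)
}

# A deterministic two-block weighted graph with strong in-block edges.
planted_graph <- function(n_per_block = 5, w_in = 10, w_between = 0.5) {
  nodes <- sprintf("N%02d", seq_len(2 * n_per_block))
  blocks <- rep(1:2, each = n_per_block)
  edges <- list()
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      w <- if (blocks[i] == blocks[j]) w_in else w_between
      edges[[length(edges) + 1]] <- tibble::tibble(
        country_a = nodes[i], country_b = nodes[j], weight = w)
    }
  }
  list(edges = dplyr::bind_rows(edges), blocks = blocks, nodes = nodes)
}

small_config <- function(blocks = list(), ...) {
  synthetic_config(blocks = blocks, ...)
}

# Total pairwise collaboration weight via the row-sum identity.
total_collaboration_weight_for_test <- function(m) {
  k <- Matrix::rowSums(m)
  sum(k * (k - 1) / 2)
}
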