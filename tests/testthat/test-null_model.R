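test_that("curveball randomization preserves margins exactly", {
  set.seed(41)
  for (rep in 1:10) {
    codes <- LETTERS[1:7]
    sets <- replicate(25, sort(sample(codes, sample(2:4, 1))), simplify = FALSE)
    tr <- make_trials(paste0("T", seq_along(sets)), 2010, "industry", sets)
    m <- build_incidence(tr, "industry")
    r <- randomize_fixed_margins(m, seed = rep)
    expect_equal(Matrix::rowSums(r), Matrix::rowSums(m))
    expect_equal(Matrix::colSums(r), Matrix::colSums(m))
    expect_true(all(r@x == 1))
  }
})

test_that("a 2x2 identity-margin matrix randomizes within its two-member fill class", {
  m <- make_incidence(list(c(1, 1, 0, 0), c(0, 0, 1, 1)), c("A", "B", "C", "D"))
  # row sums (2,2), col sums (1,1,1,1): trades can swap columns between rows
  seen <- character()
  for (s in 1:20) {
    r <- randomize_fixed_margins(m, seed = s)
    seen <- c(seen, paste(as.vector(as.matrix(r)), collapse = ""))
    expect_equal(unname(Matrix::rowSums(r)), c(2, 2))
    expect_equal(unname(Matrix::colSums(r)), rep(1, 4))
  }
  fc <- enumerate_fill_class(as.matrix(m))
  keys <- vapply(fc, function(x) paste(as.vector(x), collapse = ""), "")
  expect_true(all(seen %in% keys))
})

test_that("randomization is deterministic given a seed", {
  m <- make_incidence(list(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1)), c("A", "B", "C"))
  r1 <- randomize_fixed_margins(m, seed = 99)
  r2 <- randomize_fixed_margins(m, seed = 99)
  expect_identical(as.matrix(r1), as.matrix(r2))
})

test_that("curveball sampling is uniform over an exhaustively enumerated fill class", {
  # 4x4 fixture; chi-square against the uniform distribution on the class
  m <- make_incidence(list(c(1, 1, 0, 0), c(0, 1, 1, 0), c(0, 0, 1, 1), c(1, 0, 0, 1)),
                      c("A", "B", "C", "D"))
  fc <- enumerate_fill_class(as.matrix(m))
  keys <- vapply(fc, function(x) paste(as.vector(x), collapse = ""), "")
  rs0 <- lapply(seq_len(nrow(m)), function(i) which(as.matrix(m)[i, ] == 1) - 1L)
  n_draws <- 50000
  set.seed(7)
  draws <- character(n_draws)
  for (d in seq_len(n_draws)) {
    rs <- trialscape:::cpp_curveball(rs0, ncol(m), 20L)
    mat <- matrix(0L, nrow(m), ncol(m))
    for (i in seq_along(rs)) mat[i, rs[[i]] + 1L] <- 1L
    draws[d] <- paste(as.vector(mat), collapse = "")
  }
  expect_true(all(draws %in% keys))
  counts <- table(factor(draws, levels = keys))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("empirical percentile is the ceiling-order statistic", {
  expect_equal(empirical_q999(rep(5, 2000)), 5)
  expect_equal(empirical_q999(1:1000), 999)
  expect_equal(empirical_percentile(c(3, 1, 2), 0.5), 2)
  # sort-based oracle on random samples
  set.seed(51)
  for (rep in 1:10) {
    x <- stats::rpois(sample(100:5000, 1), lambda = stats::runif(1, 1, 20))
    expect_equal(empirical_q999(x), sort(x)[ceiling(0.999 * length(x))])
  }
})

test_that("a forced single-row matrix yields a constant null and no flag", {
  m <- make_incidence(list(c(1, 1)), c("A", "B"))
  sm <- suppressWarnings(null_distributions(m, n_reps = 200, seed = 1))
  expect_equal(sm$null_mean, 1)
  expect_equal(sm$null_q999, 1)
  expect_false(sm$flagged)
})

test_that("sampled null distributions match exhaustive fill-class enumeration", {
  # all row sums 2, all column sums 2: the fill class has 6 members
  fix <- generate_fill_class_fixture()
  expect_length(fix$fill_class, 6)
  for (fc_m in fix$fill_class) {
    expect_equal(rowSums(fc_m), rowSums(as.matrix(fix$matrix)))
    expect_equal(colSums(fc_m), colSums(as.matrix(fix$matrix)))
  }
  n_reps <- 20000
  sm <- null_distributions(fix$matrix, n_reps = n_reps, seed = 13)
  # exact per-pair distribution by enumeration
  pair_cols <- utils::combn(colnames(fix$matrix), 2, simplify = FALSE)
  for (pc in pair_cols) {
    samples <- vapply(fix$fill_class,
                      function(x) sum(x[, pc[1]] * x[, pc[2]]), numeric(1))
    exact_mean <- mean(samples)
    exact_var <- mean(samples^2) - exact_mean^2
    row <- sm[sm$country_a == pc[1] & sm$country_b == pc[2], ]
    se <- sqrt(exact_var / n_reps)
    expect_lt(abs(row$null_mean - exact_mean), max(3 * se, 1e-9))
    # q999 must be an attainable value of the exact distribution
    expect_true(row$null_q999 %in% samples)
  }
})

test_that("chain and independent modes agree with each other and with a vegan cross-check", {
  set.seed(61)
  codes <- LETTERS[1:6]
  sets <- replicate(40, sort(sample(codes, sample(2:3, 1))), simplify = FALSE)
  tr <- make_trials(paste0("T", seq_along(sets)), 2010, "industry", sets)
  m <- build_incidence(tr, "industry")
  n_reps <- 4000
  sm_chain <- null_distributions(m, n_reps = n_reps, seed = 1, mode = "chain")
  sm_indep <- null_distributions(m, n_reps = n_reps, seed = 2, mode = "independent")
  expect_equal(sm_chain$null_mean, sm_indep$null_mean, tolerance = 0.08)

  # independent reference sampler: vegan's curveball null model
  skip_if_not_installed("vegan")
  comm <- as.matrix(m)
  nm <- vegan::nullmodel(comm, "curveball")
  sims <- stats::simulate(nm, nsim = n_reps, seed = 3)
  pair_cols <- utils::combn(seq_len(ncol(m)), 2, simplify = FALSE)
  veg_mean <- vapply(pair_cols, function(pc) {
    mean(apply(sims, 3, function(s) sum(s[, pc[1]] * s[, pc[2]])))
  }, numeric(1))
  expect_equal(sm_chain$null_mean, veg_mean, tolerance = 0.08)
})

test_that("identical seeds reproduce identical null summaries", {
  m <- make_incidence(list(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1), c(1, 1, 1)),
                      c("A", "B", "C"))
  s1 <- null_distributions(m, n_reps = 1500, seed = 5)
  s2 <- null_distributions(m, n_reps = 1500, seed = 5)
  expect_identical(s1, s2)
})

test_that("small replicate counts trigger the instability warning", {
  m <- make_incidence(list(c(1, 1), c(1, 1)), c("A", "B"))
  expect_warning(null_distributions(m, n_reps = 100, seed = 1), "unstable")
})

test_that("overrepresentation degree satisfies its boundary identities", {
  expect_equal(overrep_degree(10, 4, 8), 1.5)
  expect_equal(overrep_degree(4, 4, 8), 0)   # observed at the null mean
  expect_equal(overrep_degree(8, 4, 8), 1)   # observed at the percentile
  expect_true(is.na(overrep_degree(5, 3, 3))) # degenerate null
})

test_that("the co-occurrence network contains exactly the flagged, non-degenerate pairs", {
  sm <- tibble::tibble(
    country_a = c("A", "A", "B"), country_b = c("B", "C", "C"),
    observed = c(10L, 2L, 7L), null_mean = c(4, 2, 7),
    null_q999 = c(8, 2, 7), n_reps = 1000L,
    flagged = c(TRUE, FALSE, TRUE)
  )
  net <- build_cooccurrence_network(sm)
  expect_equal(nrow(net), 1)
  expect_equal(net$degree, 1.5)
  expect_equal(attr(net, "nodes"), c("A", "B"))
  degen <- attr(net, "degenerate")
  expect_equal(nrow(degen), 1)
  expect_equal(degen$country_a, "B")

  none <- build_cooccurrence_network(dplyr::mutate(sm, flagged = FALSE))
  expect_equal(nrow(none), 0)
  iso <- build_cooccurrence_network(sm, include_isolated = TRUE)
  expect_equal(attr(iso, "nodes"), c("A", "B", "C"))
})

test_that("a stronger planted affinity never lowers the block's mean overrep degree (matched seeds)", {
  members <- c("DE", "FR", "GB", "IT", "ES")
  mean_deg <- c()
  for (aff in c(1, 3, 5)) {
    blocks <- if (aff > 1) list(list(members = members, affinity = aff)) else list()
    cfg <- synthetic_config(blocks = blocks)
    tr <- generate_registry(cfg, seed = 71, rate_scale = 0.08)
    m <- build_incidence(tr, "industry")
    mt <- trim_incidence(m, 0.95)
    sm <- null_distributions(mt, n_reps = 2000, seed = 72)
    in_block <- sm$country_a %in% members & sm$country_b %in% members
    deg <- overrep_degree(sm$observed, sm$null_mean, sm$null_q999)
    mean_deg <- c(mean_deg, mean(deg[in_block], na.rm = TRUE))
  }
  expect_true(all(diff(mean_deg) > 0))
})

test_that("affinity-5 planted blocks are recovered with high within-block sensitivity", {
  blocks <- list(
    list(members = c("DE", "FR", "GB", "IT", "ES"), affinity = 5),
    list(members = c("US", "CA", "MX", "BR", "AR"), affinity = 5)
  )
  cfg <- synthetic_config(blocks = blocks)
  tr <- generate_registry(cfg, seed = 11, rate_scale = 0.4)
  ind <- tr$countries[tr$sponsor_type == "industry"]
  n_block_trials <- vapply(blocks, function(b) {
    sum(vapply(ind, function(s) sum(s %in% b$members) >= 2, logical(1)))
  }, numeric(1))
  expect_true(all(n_block_trials >= 200)) # study precondition

  mt <- trim_incidence(build_incidence(tr, "industry"), 0.95)
  sm <- null_distributions(mt, n_reps = 5000, seed = 12)
  b1 <- blocks[[1]]$members
  b2 <- blocks[[2]]$members
  within <- (sm$country_a %in% b1 & sm$country_b %in% b1) |
    (sm$country_a %in% b2 & sm$country_b %in% b2)
  cross <- (sm$country_a %in% b1 & sm$country_b %in% b2) |
    (sm$country_a %in% b2 & sm$country_b %in% b1)
  expect_gte(mean(sm$flagged[within]), 0.9)
  expect_lte(mean(sm$flagged[cross]), 0.01)

  # the resulting co-occurrence network carries the planted structure
  net <- build_cooccurrence_network(sm)
  expect_true(all(net$degree[(net$country_a %in% b1 & net$country_b %in% b1) |
                               (net$country_a %in% b2 & net$country_b %in% b2)] > 1))
})
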