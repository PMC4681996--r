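test_that("trial_density follows the per-million definition", {
  expect_equal(trial_density(10, 1e6), 10)
  expect_equal(trial_density(0, 5e6), 0)
  expect_equal(trial_density(6457, 10e6), 645.7)
  expect_error(trial_density(5, 0), "positive")
  # linear in the trial count
  expect_equal(trial_density(24, 3e6), 2 * trial_density(12, 3e6))
})

test_that("group medians use the sorted-middle convention and skip empty groups", {
  d <- tibble::tibble(
    country = paste0("C", 1:5),
    n_trials = 1:5,
    density = c(1, 2, 3, 1, 3),
    eligible = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    population_2012 = rep(1e6, 5),
    income_group = factor(c("high", "high", "high", "low", "low"),
                          levels = c("high", "upper_middle", "lower_middle", "low")),
    region = "Asia", continent = "Asia"
  )
  med <- group_median_density(d, by = "income_group")
  expect_equal(med$median_density[med$income_group == "high"], 2)  # odd group
  expect_equal(med$median_density[med$income_group == "low"], 2)   # even: midpoint of 1,3
  expect_false("upper_middle" %in% as.character(med$income_group)) # empty absent
})

test_that("group medians match a direct sort oracle on random fixtures", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    d <- tibble::tibble(
      country = paste0("C", seq_len(n)),
      n_trials = 1L,
      density = round(stats::runif(n, 0, 300), 1),
      eligible = stats::runif(n) > 0.2,
      population_2012 = 1e6,
      income_group = factor(sample(c("high", "low"), n, replace = TRUE),
                            levels = c("high", "upper_middle", "lower_middle", "low")),
      region = "Asia", continent = "Asia"
    )
    med <- group_median_density(d, by = "income_group")
    for (g in as.character(med$income_group)) {
      vals <- sort(d$density[d$eligible & d$income_group == g])
      n_v <- length(vals)
      oracle <- if (n_v %% 2 == 1) vals[(n_v + 1) / 2] else
        (vals[n_v / 2] + vals[n_v / 2 + 1]) / 2
      expect_equal(med$median_density[as.character(med$income_group) == g], oracle)
    }
  }
})

test_that("density_table counts every country location once per trial", {
  tr <- make_trials(c("T1", "T2"), c(2008, 2009),
                    c("industry", "industry"),
                    list(c("FR", "DE"), "FR"))
  d <- density_table(tr)
  expect_equal(d$n_trials[d$country == "FR"], 2L)
  expect_equal(d$n_trials[d$country == "DE"], 1L)
  expect_equal(d$n_trials[d$country == "US"], 0L)
  ct <- country_table()
  expect_equal(d$density[d$country == "FR"],
               2e6 / ct$population_2012[ct$code == "FR"])
})

test_that("classify_scope distinguishes single-country and uni/inter-continental trials", {
  tr <- make_trials(paste0("T", 1:3), rep(2010, 3), rep("industry", 3),
                    list("FR", c("FR", "DE"), c("FR", "US")))
  sc <- classify_scope(tr)
  expect_equal(as.character(sc$scope),
               c("single_country", "international_unicontinental",
                 "international_intercontinental"))
  # permutation invariance of the country set
  tr2 <- make_trials("T1", 2010, "industry", list(c("US", "FR")))
  expect_equal(as.character(classify_scope(tr2)$scope),
               "international_intercontinental")
  bad <- make_trials("T1", 2010, "industry", list(c("FR", "XX")))
  expect_error(classify_scope(bad), "continent")
})

test_that("sponsorship and international shares apply the 50-trial reportability rule", {
  sets <- c(rep(list("FR"), 6), rep(list(c("FR", "DE"))), rep(list("DE"), 3))
  tr <- make_trials(paste0("T", 1:10), rep(2010, 10),
                    c(rep("industry", 4), rep("non_industry", 6)),
                    sets)
  ss <- sponsorship_share(tr)
  expect_equal(ss$denominator[ss$country == "FR"], 7L)
  expect_equal(ss$numerator[ss$country == "FR"], 4L)
  expect_equal(ss$share[ss$country == "FR"], 4 / 7)
  expect_false(any(ss$reportable)) # all denominators below 50

  big <- make_trials(paste0("B", 1:60), rep(2010, 60),
                     rep(c("industry", "non_industry"), 30),
                     c(rep(list(c("FR", "DE")), 30), rep(list("FR"), 30)))
  ss2 <- sponsorship_share(big)
  expect_true(ss2$reportable[ss2$country == "FR"])  # 60 >= 50
  expect_false(ss2$reportable[ss2$country == "DE"]) # 30 < 50
  # industry trials: 15 international {FR,DE} + 15 single-country {FR}
  is2 <- international_share(big, "industry")
  expect_equal(is2$denominator[is2$country == "FR"], 30L)
  expect_equal(is2$share[is2$country == "FR"], 0.5)
  expect_false(is2$reportable[is2$country == "FR"])
})

test_that("single-country plus international trials partition each country's total", {
  cfg <- synthetic_config()
  tr <- generate_registry(cfg, seed = 5, rate_scale = 0.01)
  d_all <- density_table(tr)
  d_single <- density_table(tr, international = FALSE)
  d_intl <- density_table(tr, international = TRUE)
  expect_equal(d_all$n_trials, d_single$n_trials + d_intl$n_trials)
})

test_that("annual distributions count per country-location and sum to one", {
  tr <- make_trials(paste0("T", 1:3), c(2006, 2006, 2007),
                    rep("industry", 3),
                    list(c("FR", "DE"), c("BR", "AR"), "US"))
  ad <- annual_distribution(tr, by = "region")
  y6 <- ad[ad$year == 2006, ]
  # one FR+DE trial -> two Western Europe locations; BR+AR -> two South America
  expect_equal(y6$n_locations[y6$region == "Western Europe"], 2L)
  expect_equal(y6$n_locations[y6$region == "South America"], 2L)
  expect_equal(sum(y6$share), 1)
  expect_equal(ad$share[ad$year == 2007], 1)

  # shares sum to one per year on synthetic data too
  syn <- generate_registry(synthetic_config(), seed = 3, rate_scale = 0.005)
  ad2 <- annual_distribution(syn, by = "income_group")
  sums <- tapply(ad2$share, ad2$year, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("single-region trial gives that region the full 2006 share", {
  tr <- make_trials("T1", 2006, "industry", list(c("FR", "DE")))
  ad <- annual_distribution(tr, by = "region")
  expect_equal(ad$share[ad$region == "Western Europe"], 1)
})
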