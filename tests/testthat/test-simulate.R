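test_that("population table generation follows the arithmetic progression", {
  strata <- tibble::tibble(region = "East", gender = "All")
  flat <- generate_population_table(strata, 1999:2003, base_sizes = 1e6)
  expect_true(all(flat$population == 1e6))
  growing <- generate_population_table(strata, 1999:2000, base_sizes = 1e6,
                                       annual_growth = 36500)
  expect_equal(growing$population, c(1e6, 1036500))
  expect_error(generate_population_table(strata, c(1999, 2001), 1e6),
               "contiguous")
  expect_error(generate_population_table(strata, 1999:2001, 1e6,
                                         annual_growth = -1e6),
               "zero or below")
  expect_error(generate_population_table(strata, 1999, 0), "> 0")
})

test_that("noise-free simulation reproduces the expected counts exactly", {
  strata <- tibble::tibble(region = "East", gender = "All")
  beta <- c(0.2, rep(0, 9))
  model <- true_model(coefficients = beta, strata = strata, noise = "none")
  pop <- flat_population(strata, 1e6)
  s <- simulate_monthly_counts(model, pop, 1:286)
  expect_true(all(s$deaths == 2))
  expect_true(all(s$rate == 0.2))
  expect_equal(s$true_rate, rep(0.2, 286))
})

test_that("poisson noise has the right mean and is seed-deterministic", {
  strata <- tibble::tibble(region = "East", gender = "All")
  beta <- c(0.5, rep(0, 9))  # lambda = 0.5 * 1e7 / 1e5 = 50 per month
  model <- true_model(coefficients = beta, strata = strata, noise = "poisson")
  pop <- flat_population(strata, 1e7, years = 1999:2832)
  months <- 1:10000
  s <- simulate_monthly_counts(model, pop, months, seed = 5)
  expect_true(all(s$deaths >= 0 & s$deaths %% 1 == 0))
  expect_lt(abs(mean(s$deaths) - 50), 3 * sqrt(50 / length(months)))
  s2 <- simulate_monthly_counts(model, pop, months, seed = 5)
  expect_identical(s$deaths, s2$deaths)
  s3 <- simulate_monthly_counts(model, pop, months, seed = 6)
  expect_false(identical(s$deaths, s3$deaths))
  expect_error(simulate_monthly_counts(model, pop, months), "seed")
})

test_that("empirical rates converge to the true rate under large populations", {
  model <- default_true_model()
  pop <- default_population_table()
  s <- simulate_monthly_counts(model, pop, 1:286, seed = 21)
  # standardized deviations pool to mean zero at 3-sigma Monte-Carlo tolerance
  lam <- s$true_rate * s$population / 1e5
  z <- (s$deaths - lam) / sqrt(lam)
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  # individual months exceed 3 sigma only at the rate chance allows
  expect_lt(mean(abs(z) > 3), 0.01)
})

test_that("negative expected rates are rejected naming the month", {
  strata <- tibble::tibble(region = "East", gender = "All")
  beta <- c(0.2, -0.01, rep(0, 8))  # goes negative at t = 21
  model <- true_model(coefficients = beta, strata = strata, noise = "none")
  pop <- flat_population(strata, 1e6)
  expect_error(simulate_monthly_counts(model, pop, 1:286),
               "t=21.*2000-09|negative expected rate")
})

test_that("coefficient vectors must match the timeline's design columns", {
  strata <- tibble::tibble(region = "East", gender = "All")
  expect_error(true_model(coefficients = rep(0, 7), strata = strata),
               "timeline implies 10")
})

test_that("certificates conserve counts and contaminants all fail the filter", {
  strata <- tibble::tibble(region = "East", gender = "All")
  beta <- c(2, rep(0, 9))
  model <- true_model(coefficients = beta, strata = strata, noise = "poisson")
  pop <- flat_population(strata, 1e6)
  s <- simulate_monthly_counts(model, pop, 1:50, seed = 8)

  # closed loop at contaminant fraction zero
  certs0 <- simulate_certificates(s, contaminant_fraction = 0, seed = 9)
  expect_identical(nrow(certs0), as.integer(sum(s$deaths)))
  expect_true(all(opioid_filter_matches(certs0)))

  certs <- simulate_certificates(s, contaminant_fraction = 0.3, seed = 9)
  n_base <- sum(s$deaths)
  n_cont <- sum(certs$contaminant)
  expect_identical(n_cont, as.integer(round(n_base * 0.3 / 0.7)))
  expect_identical(nrow(certs), as.integer(n_base + n_cont))
  # the filter recovers exactly the non-contaminant records
  keep <- opioid_filter_matches(certs)
  expect_identical(keep, !certs$contaminant)
  # per-month counts of filter survivors equal the simulated series
  kept <- dplyr::count(
    dplyr::mutate(filter_opioid_deaths(certs),
                  ym = format(date, "%Y-%m")), ym)
  sim <- dplyr::summarise(
    dplyr::group_by(s, ym = format(date, "%Y-%m")),
    n = sum(deaths), .groups = "drop")
  joined <- dplyr::left_join(sim, kept, by = "ym")
  expect_equal(joined$n.y, joined$n.x)

  expect_error(simulate_certificates(s, contaminant_fraction = 1, seed = 1),
               "\\[0, 1\\)")
})

test_that("WONDER fixtures round-trip through parse and merge", {
  strata <- tibble::tibble(region = c("East", "East"),
                           gender = c("Female", "Male"))
  model <- true_model(coefficients = c(1, 0.005, rep(0, 8)), strata = strata,
                      noise = "poisson")
  pop <- flat_population(strata, 5e6)
  s <- simulate_monthly_counts(model, pop, 1:286, seed = 13)
  dir <- withr::local_tempdir()
  paths <- write_wonder_fixture(s, dir, suppress_below = 0, split = "2020-12")
  final <- parse_wonder_export(paths$final, "final")
  prov <- parse_wonder_export(paths$provisional, "provisional")
  merged <- merge_final_provisional(final, prov, cutoff = "2020-12")
  s_sorted <- dplyr::arrange(s, region, gender, year, month)
  expect_identical(nrow(merged), nrow(s_sorted))
  expect_equal(merged$count, as.integer(s_sorted$deaths))
  expect_identical(unique(merged$provenance[merged$year <= 2020]), "final")
  expect_identical(unique(merged$provenance[merged$year >= 2021]), "provisional")
})

test_that("suppression replaces small cells with the literal token", {
  series <- tibble::tibble(region = "East", gender = "All",
                           year = 1999L, month = 1:3,
                           deaths = c(7, 10, 25))
  dir <- withr::local_tempdir()
  paths <- write_wonder_fixture(series, dir, suppress_below = 10,
                                split = "1999-12")
  raw <- readLines(paths$final)
  expect_true(any(grepl("\tSuppressed$", raw)))
  tab <- parse_wonder_export(paths$final)
  expect_true(is.na(tab$count[tab$month == 1]))
  expect_true(tab$suppressed[tab$month == 1])
  expect_identical(tab$count[tab$month == 2], 10L)  # cutoff is strict
  expect_identical(tab$count[tab$month == 3], 25L)
})

test_that("a split before all data yields an empty final file that still merges", {
  series <- tibble::tibble(region = "East", gender = "All",
                           year = 2005L, month = 1:6,
                           deaths = c(20, 21, 22, 23, 24, 25))
  dir <- withr::local_tempdir()
  paths <- write_wonder_fixture(series, dir, suppress_below = 0,
                                split = "1999-01")
  final <- parse_wonder_export(paths$final, "final")
  prov <- parse_wonder_export(paths$provisional, "provisional")
  expect_identical(nrow(final), 0L)
  expect_identical(nrow(prov), 6L)
  merged <- merge_final_provisional(final, prov, cutoff = "1999-01")
  expect_equal(merged$count, as.integer(series$deaths))
})

test_that("gaussian AR(1) noise option produces autocorrelated rates", {
  strata <- tibble::tibble(region = "East", gender = "All")
  model <- true_model(coefficients = c(5, rep(0, 9)), strata = strata,
                      noise = "gaussian", sd = 0.3, ar1 = 0.8)
  pop <- flat_population(strata, 1e7, years = 1999:2600)
  s <- simulate_monthly_counts(model, pop, 1:5000, seed = 2)
  resid <- s$rate - s$true_rate
  expect_gt(cor(resid[-1], resid[-length(resid)]), 0.6)
})
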