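test_that("poisson resampling is mean-preserving, degenerate at zero, seeded", {
  expect_true(all(poisson_resample(rep(0L, 1000), seed = 1) == 0L))
  draws <- poisson_resample(rep(100L, 10000), seed = 2)
  expect_lt(abs(mean(draws) - 100), 3 * sqrt(100 / 10000))
  expect_identical(poisson_resample(1:50, seed = 3),
                   poisson_resample(1:50, seed = 3))
  expect_false(identical(poisson_resample(1:50, seed = 3),
                         poisson_resample(1:50, seed = 4)))
  expect_error(poisson_resample(c(1, -1), seed = 1), "non-negative")
})

test_that("B = 2 bounds equal the min and max of the two replicates", {
  strata <- tibble::tibble(region = "East", gender = "All")
  model <- true_model(coefficients = south_beta(), strata = strata,
                      noise = "poisson")
  pop <- flat_population(strata, 1e7)
  s <- simulate_monthly_counts(model, pop, 1:286, seed = 30)
  # inverse-ECDF quantiles (type 1) hit the replicate min and max exactly
  b <- bootstrap_cumulative_excess(s, B = 2, seed = 31, qtype = 1)
  expect_identical(ncol(b$replicates), 2L)
  expect_equal(b$ci$lower, pmin(b$replicates[, 1], b$replicates[, 2]))
  expect_equal(b$ci$upper, pmax(b$replicates[, 1], b$replicates[, 2]))
  # the default interpolating estimator stays inside the replicate range
  b7 <- bootstrap_cumulative_excess(s, B = 2, seed = 31)
  expect_true(all(b7$ci$lower >= b$ci$lower & b7$ci$upper <= b$ci$upper))
  expect_error(bootstrap_cumulative_excess(s, B = 1, seed = 1), "at least 2")
  expect_error(bootstrap_cumulative_excess(s, B = 10, seed = 1,
                                           levels = c(0, 1)),
               "inside")
})

test_that("replicates are seed-deterministic and the point matches the fit", {
  strata <- tibble::tibble(region = "East", gender = "All")
  model <- true_model(coefficients = south_beta(), strata = strata,
                      noise = "poisson")
  pop <- flat_population(strata, 1e7)
  s <- simulate_monthly_counts(model, pop, 1:286, seed = 40)
  b1 <- bootstrap_cumulative_excess(s, B = 50, seed = 41)
  b2 <- bootstrap_cumulative_excess(s, B = 50, seed = 41)
  expect_identical(b1$replicates, b2$replicates)
  # point estimate equals the non-bootstrap pipeline's cumulative excess
  X <- build_design_matrix(s$t)
  fit <- fit_its(X, s$rate)
  post <- s$t >= 255
  cf <- counterfactual_predict(fit, counterfactual_design(unclass(X)[post, ]))
  ex <- excess_series(s$t[post], s$rate[post], cf, s$population[post])
  expect_equal(b1$ci$point, ex$cumulative_excess, tolerance = 1e-8)
})

test_that("a null COVID scenario yields a CI containing zero", {
  strata <- tibble::tibble(region = "East", gender = "All")
  beta <- south_beta()
  beta[c("Indicator_COVID", "MonthsSince_COVID", "MonthsSince_CHW")] <- 0
  model <- true_model(coefficients = beta, strata = strata, noise = "poisson")
  pop <- flat_population(strata, 1e7)
  s <- simulate_monthly_counts(model, pop, 1:286, seed = 50)
  b <- bootstrap_cumulative_excess(s, B = 200, seed = 51)
  last <- nrow(b$ci)
  expect_lte(b$ci$lower[last], 0)
  expect_gte(b$ci$upper[last], 0)
})

test_that("CI width shrinks as the population (hence count signal) grows", {
  strata <- tibble::tibble(region = "East", gender = "All")
  model <- true_model(coefficients = south_beta(), strata = strata,
                      noise = "poisson")
  widths <- vapply(c(1e6, 1e8), function(sz) {
    pop <- flat_population(strata, sz)
    s <- simulate_monthly_counts(model, pop, 1:286, seed = 60)
    b <- bootstrap_cumulative_excess(s, B = 100, seed = 61)
    last <- nrow(b$ci)
    (b$ci$upper[last] - b$ci$lower[last]) / b$ci$point[last]
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("national replicates are region-paired sums with matching point", {
  strata <- tibble::tibble(region = "East", gender = "All")
  model <- true_model(coefficients = south_beta(), strata = strata,
                      noise = "poisson")
  pop <- flat_population(strata, 1e7)
  s1 <- simulate_monthly_counts(model, pop, 1:286, seed = 70)
  s2 <- simulate_monthly_counts(model, pop, 1:286, seed = 71)
  b1 <- bootstrap_cumulative_excess(s1, B = 80, seed = 72)
  b2 <- bootstrap_cumulative_excess(s2, B = 80, seed = 73)
  nat <- national_bootstrap(list(A = b1, B = b2))
  expect_equal(nat$replicates, b1$replicates + b2$replicates)
  expect_equal(nat$ci$point, b1$ci$point + b2$ci$point)
  # permuting region order changes nothing
  nat2 <- national_bootstrap(list(B = b2, A = b1))
  expect_equal(nat2$ci, nat$ci)
  # a region with all-zero replicates is the additive identity
  zero <- b1
  zero$replicates[] <- 0
  zero$ci$point[] <- 0
  nat3 <- national_bootstrap(list(A = b1, Z = zero))
  expect_equal(nat3$ci$lower,
               apply(b1$replicates, 1, quantile, probs = 0.025, names = FALSE))
  bad <- bootstrap_cumulative_excess(s2, B = 40, seed = 74)
  expect_error(national_bootstrap(list(A = b1, B = bad)), "same number")
})
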