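#' Define a piecewise-linear ITS truth for simulation
#'
#' A `true_model` couples an intervention timeline with one coefficient
#' vector per stratum (the segmented-regression coefficients, in deaths per
#' 100,000 for levels and per 100,000 per month for slopes) and a noise
#' mechanism. It is the data-generating process for the synthetic monthly
#' series: the expected rate at month t is the design row at t times the
#' stratum's coefficients.
#'
#' @param timeline an [intervention_timeline()].
#' @param coefficients either a single numeric vector (recycled across
#'   strata) or a named list keyed `"region/gender"`; each vector must have
#'   one entry per design column implied by the timeline (named vectors are
#'   checked against the column names).
#' @param strata tibble with columns `region`, `gender`.
#' @param noise `"poisson"` (counts drawn Poisson with the implied mean),
#'   `"gaussian"` (Gaussian noise of sd `sd` added to the rate, optionally
#'   AR(1)-correlated via `ar1`), or `"none"`.
#' @param sd rate-noise standard deviation (gaussian noise only), deaths per
#'   100,000.
#' @param ar1 AR(1) coefficient for gaussian rate noise; 0 = independent.
#' @return object of class `true_model`.
#' @export
true_model <- function(timeline = default_timeline(), coefficients, strata,
                       noise = c("poisson", "gaussian", "none"),
                       sd = 0.1, ar1 = 0) {
  noise <- match.arg(noise)
  stopifnot(all(c("region", "gender") %in% names(strata)))
  cols <- design_column_names(timeline)
  keys <- paste(strata$region, strata$gender, sep = "/")
  if (!is.list(coefficients)) {
    coefficients <- stats::setNames(rep(list(coefficients), length(keys)), keys)
  }
  if (!all(keys %in% names(coefficients))) {
    stop("coefficients missing for stratum: ",
         paste(setdiff(keys, names(coefficients)), collapse = ", "),
         call. = FALSE)
  }
  coefficients <- lapply(coefficients[keys], function(b) {
    if (length(b) != length(cols)) {
      stop(sprintf("coefficient vector has %d entries; timeline implies %d columns (%s)",
                   length(b), length(cols), paste(cols, collapse = ", ")),
           call. = FALSE)
    }
    if (!is.null(names(b)) && !identical(names(b), cols)) b <- b[cols]
    stats::setNames(as.numeric(b), cols)
  })
  if (abs(ar1) >= 1) stop("`ar1` must lie strictly inside (-1, 1)", call. = FALSE)
  structure(
    list(timeline = timeline, coefficients = coefficients,
         strata = tibble::as_tibble(strata[, c("region", "gender")]),
         noise = noise, sd = sd, ar1 = ar1),
    class = "true_model"
  )
}

#' Default synthetic scenario: four Census Regions under published trends
#'
#' Uses the bundled published regional ITS coefficient estimates as the
#' truth for the four Census Regions (gender-aggregated), with Poisson count
#' noise — the realistic regime for parameter-recovery experiments.
#'
#' @param noise noise mechanism, passed through to [true_model()].
#' @param sd,ar1 gaussian-noise parameters, passed through.
#' @return a `true_model` over strata Northeast/Midwest/South/West, gender
#'   `"All"`.
#' @export
default_true_model <- function(noise = "poisson", sd = 0.1, ar1 = 0) {
  coefs <- regional_its_coefficients()
  strata <- tibble::tibble(region = coefs$region, gender = "All")
  cl <- stats::setNames(
    lapply(seq_len(nrow(coefs)), function(i) unlist(coefs[i, -1])),
    paste(coefs$region, "All", sep = "/")
  )
  true_model(default_timeline(), cl, strata, noise = noise, sd = sd, ar1 = ar1)
}

#' Annual July-1 population anchors for a synthetic scenario
#'
#' Builds one anchor per stratum per year as an arithmetic progression:
#' `base + growth * (year - years[1])`.
#'
#' @param strata tibble with `region`, `gender`.
#' @param years contiguous integer years.
#' @param base_sizes starting (first-year) population per stratum: a single
#'   number or a vector/list named `"region/gender"`.
#' @param annual_growth persons added per year (same shapes as
#'   `base_sizes`); default 0.
#' @return tibble `region`, `gender`, `year`, `population`.
#' @export
generate_population_table <- function(strata, years, base_sizes,
                                      annual_growth = 0) {
  years <- as.integer(years)
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop("`years` must be contiguous", call. = FALSE)
  }
  keys <- paste(strata$region, strata$gender, sep = "/")
  pick <- function(x, key) {
    if (length(x) == 1 && is.null(names(x))) return(as.numeric(x))
    if (is.null(names(x)) || !key %in% names(x)) {
      stop("no value for stratum ", key, call. = FALSE)
    }
    as.numeric(x[[key]])
  }
  out <- lapply(seq_along(keys), function(i) {
    base <- pick(base_sizes, keys[i])
    growth <- pick(annual_growth, keys[i])
    if (base <= 0) stop("base population must be > 0", call. = FALSE)
    pop <- base + growth * (years - years[1])
    if (any(pop <= 0)) {
      stop("population would reach zero or below for stratum ", keys[i],
           call. = FALSE)
    }
    tibble::tibble(region = strata$region[i], gender = strata$gender[i],
                   year = years, population = pop)
  })
  dplyr::bind_rows(out)
}

#' Default population anchors: plausible Census Region totals
#'
#' Round-number approximations of the four regions' resident populations
#' (persons, July-1): linear growth from 1999 levels.
#'
#' @param years integer years (default 1999:2023).
#' @return tibble as from [generate_population_table()].
#' @export
default_population_table <- function(years = 1999:2023) {
  strata <- tibble::tibble(
    region = c("Northeast", "Midwest", "South", "West"),
    gender = "All"
  )
  generate_population_table(
    strata, years,
    base_sizes = c("Northeast/All" = 53.6e6, "Midwest/All" = 64.4e6,
                   "South/All" = 100.2e6, "West/All" = 63.2e6),
    annual_growth = c("Northeast/All" = 0.15e6, "Midwest/All" = 0.25e6,
                      "South/All" = 1.30e6, "West/All" = 0.70e6)
  )
}

#' Simulate monthly opioid death counts from a known truth
#'
#' For each stratum, evaluates the true expected rate `mu_t` from the
#' model's design and coefficients over the month range, converts to an
#' expected count `mu_t * p_t / 100000` using the day-interpolated month-end
#' population, and draws counts under the configured noise: Poisson draws
#' with that mean, Gaussian rate noise back-converted to (real-valued)
#' counts, or no noise. Rejects configurations whose expected rate goes
#' negative anywhere in the range, naming the offending month.
#'
#' @param model a [true_model()].
#' @param population annual anchors tibble (`region`, `gender`, `year`,
#'   `population`).
#' @param months integer month-index range (default 1:286, Jan 1999 to Oct
#'   2022).
#' @param seed integer seed; required when the model has noise.
#' @return tibble `region`, `gender`, `t`, `year`, `month`, `date`,
#'   `deaths`, `population`, `rate`, `true_rate`.
#' @export
simulate_monthly_counts <- function(model, population, months = 1:286, seed = NULL) {
  stopifnot(inherits(model, "true_model"))
  if (model$noise != "none" && is.null(seed)) {
    stop("`seed` is required under stochastic noise", call. = FALSE)
  }
  months <- as.integer(months)
  X <- build_design_matrix(months, model$timeline)
  dates <- assign_month_end_dates(1999L + (months - 1L) %/% 12L,
                                  (months - 1L) %% 12L + 1L)
  sim_one <- function(i) {
    key <- paste(model$strata$region[i], model$strata$gender[i], sep = "/")
    beta <- model$coefficients[[key]]
    mu <- drop(unclass(X)[, names(beta), drop = FALSE] %*% beta)
    if (any(mu < 0)) {
      bad <- months[which(mu < 0)[1]]
      stop(sprintf("negative expected rate at month t=%d (%s) for stratum %s",
                   bad, format(index_to_date(bad), "%Y-%m"), key),
           call. = FALSE)
    }
    anch <- population[population$region == model$strata$region[i] &
                         population$gender == model$strata$gender[i], ,
                       drop = FALSE]
    if (nrow(anch) == 0) stop("no population anchors for stratum ", key,
                              call. = FALSE)
    p <- interpolate_population(anch, dates)
    lambda <- mu * p / 1e5
    deaths <- switch(
      model$noise,
      none = lambda,
      poisson = stats::rpois(length(lambda), lambda),
      gaussian = {
        e <- stats::rnorm(length(mu), 0, model$sd)
        if (model$ar1 != 0) e <- as.numeric(stats::filter(e, model$ar1,
                                                          method = "recursive"))
        pmax(0, (mu + e) * p / 1e5)
      }
    )
    tibble::tibble(
      region = model$strata$region[i], gender = model$strata$gender[i],
      t = months,
      year = 1999L + (months - 1L) %/% 12L,
      month = (months - 1L) %% 12L + 1L,
      date = dates,
      deaths = deaths,
      population = p,
      rate = compute_death_rate(deaths, p),
      true_rate = mu
    )
  }
  run <- function() dplyr::bind_rows(lapply(seq_len(nrow(model$strata)), sim_one))
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Expand a monthly count series into record-level death certificates
#'
#' For every stratum-month, emits `deaths` certificate records that satisfy
#' the opioid ICD-10 inclusion rule (underlying cause drawn from the X/Y
#' poisoning codes, contributing causes containing at least one qualifying
#' T40 code), plus a configurable admixture of contaminant records that must
#' fail the rule — either a non-poisoning underlying cause or no qualifying
#' T code. With contaminant fraction f, the number of contaminants is
#' `round(n_base * f / (1 - f))` so contaminants form fraction ~f of all
#' records. Contaminants are flagged in the `contaminant` column (generator
#' metadata, not part of the certificate proper).
#'
#' @param series tibble from [simulate_monthly_counts()] with integer
#'   `deaths`.
#' @param contaminant_fraction fraction of total records that are
#'   contaminants, in `[0, 1)`.
#' @param seed integer seed (required).
#' @return tibble `region`, `gender`, `date` (day-of-death), `underlying`,
#'   `contributing` (list-column), `contaminant` (logical).
#' @export
simulate_certificates <- function(series, contaminant_fraction = 0, seed) {
  if (contaminant_fraction < 0 || contaminant_fraction >= 1) {
    stop("`contaminant_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (any(series$deaths %% 1 != 0)) {
    stop("certificate simulation needs integer death counts", call. = FALSE)
  }
  rule <- opioid_code_rule()
  t_codes <- c("T40.0", "T40.1", "T40.2", "T40.3", "T40.4", "T40.6")
  bad_und <- c("W34", "I21", "J18", "R99", "V89")
  bad_t <- c("T51.0", "T42.4", "T43.6")
  withr::with_seed(as.integer(seed), {
    n_base <- sum(series$deaths)
    n_cont <- round(n_base * contaminant_fraction / (1 - contaminant_fraction))
    # contaminants land in random stratum-months, weighted by size
    cont_rows <- if (n_cont > 0) {
      sample(nrow(series), n_cont, replace = TRUE,
             prob = pmax(series$deaths, 1))
    } else integer(0)
    make_records <- function(row_idx, n, contaminant) {
      if (n == 0) return(NULL)
      row <- series[row_idx, ]
      last_day <- as.integer(format(row$date, "%d"))
      day <- sample(last_day, n, replace = TRUE)
      dod <- as.Date(sprintf("%d-%02d-%02d", row$year, row$month, day))
      if (!contaminant) {
        und <- sample(rule$underlying, n, replace = TRUE)
        contrib <- lapply(seq_len(n), function(j) {
          cc <- sample(t_codes, sample(1:2, 1))
          if (stats::runif(1) < 0.2) cc <- c(cc, sample(bad_t, 1))
          unique(cc)
        })
      } else {
        wrong_und <- stats::runif(n) < 0.5
        und <- ifelse(wrong_und,
                      sample(bad_und, n, replace = TRUE),
                      sample(rule$underlying, n, replace = TRUE))
        contrib <- lapply(seq_len(n), function(j) {
          if (wrong_und[j]) sample(t_codes, 1)  # wrong underlying, T irrelevant
          else if (stats::runif(1) < 0.5) character(0)  # no T at all
          else sample(bad_t, 1)  # only non-qualifying T
        })
      }
      tibble::tibble(region = row$region, gender = row$gender, date = dod,
                     underlying = und, contributing = contrib,
                     contaminant = contaminant)
    }
    base <- dplyr::bind_rows(lapply(seq_len(nrow(series)), function(i) {
      make_records(i, as.integer(series$deaths[i]), FALSE)
    }))
    cont <- if (n_cont > 0) {
      tab <- table(cont_rows)
      dplyr::bind_rows(lapply(names(tab), function(k) {
        make_records(as.integer(k), as.integer(tab[[k]]), TRUE)
      }))
    } else NULL
    out <- dplyr::bind_rows(base, cont)
    out[sample(nrow(out)), , drop = FALSE]
  })
}

#' Write a synthetic series as a WONDER-dialect final/provisional file pair
#'
#' Renders the monthly series in the tab-separated export dialect: a header
#' row, one row per Region x Gender x Year x Month, counts below the
#' suppression cutoff replaced by the literal token `"Suppressed"`, and a
#' trailing Notes block of `"---"`-prefixed lines. Months at or before
#' `split` go to the final file; later months to the provisional file, so
#' the pair round-trips through [parse_wonder_export()] and
#' [merge_final_provisional()] with `cutoff = split`.
#'
#' @param series tibble with `region`, `gender`, `year`, `month`, `deaths`
#'   (integer).
#' @param dir output directory (created if needed).
#' @param suppress_below counts strictly below this are suppressed
#'   (default 10; 0 disables suppression).
#' @param split `"YYYY-MM"`: last month written to the final file.
#' @return invisible list with elements `final` and `provisional` (paths).
#' @export
write_wonder_fixture <- function(series, dir, suppress_below = 10,
                                 split = "2020-12") {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", dir, call. = FALSE)
  }
  if (any(series$deaths %% 1 != 0)) {
    stop("WONDER fixtures need integer death counts", call. = FALSE)
  }
  cut_idx <- monthly_index(split)
  tidx <- (series$year - 1999L) * 12L + series$month
  render <- function(rows, path) {
    lines <- "Census Region\tGender\tYear\tMonth\tDeaths"
    if (nrow(rows) > 0) {
      rows <- rows[order(rows$region, rows$gender, rows$year, rows$month), ]
      deaths <- ifelse(suppress_below > 0 & rows$deaths < suppress_below,
                       "Suppressed", format(as.integer(rows$deaths),
                                            scientific = FALSE, trim = TRUE))
      lines <- c(lines, sprintf("%s\t%s\t%d\t%02d\t%s", rows$region,
                                rows$gender, rows$year, rows$month, deaths))
    }
    lines <- c(lines, "---", "--- Dataset: Synthetic Multiple Cause of Death",
               "--- Suppressed counts are below the small-cell cutoff.")
    con <- tryCatch(file(path, "w"), error = function(e) {
      stop("cannot write fixture to ", path, call. = FALSE)
    })
    on.exit(close(con))
    writeLines(lines, con)
    path
  }
  final_path <- render(series[tidx <= cut_idx, , drop = FALSE],
                       file.path(dir, "final.txt"))
  prov_path <- render(series[tidx > cut_idx, , drop = FALSE],
                      file.path(dir, "provisional.txt"))
  invisible(list(final = final_path, provisional = prov_path))
}

#' Read/write annual population anchor CSVs
#' @param table tibble `region`, `gender`, `year`, `population`.
#' @param path file path.
#' @export
write_population_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  readr::read_csv(path, col_types = "ccid", progress = FALSE)
}
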