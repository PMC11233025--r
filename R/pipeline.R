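#' Write a complete synthetic scenario to disk
#'
#' Simulates monthly counts from a truth, writes them in the WONDER dialect
#' (final + provisional pair), writes the annual population CSV, and
#' serializes the generating truth (timeline, coefficients, noise) as YAML
#' so downstream recovery can be checked against it.
#'
#' @param model a [true_model()].
#' @param population annual anchors tibble; default the bundled regional
#'   approximations.
#' @param out_dir output directory.
#' @param months month-index range (default 1:286).
#' @param seed integer seed.
#' @param suppress_below,split passed to [write_wonder_fixture()].
#' @return invisible list of file paths (`final`, `provisional`,
#'   `population`, `truth`).
#' @export
simulate_scenario <- function(model = default_true_model(),
                              population = default_population_table(),
                              out_dir, months = 1:286, seed,
                              suppress_below = 10, split = "2020-12") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  series <- simulate_monthly_counts(model, population, months, seed)
  paths <- write_wonder_fixture(series, out_dir,
                                suppress_below = suppress_below, split = split)
  pop_path <- write_population_csv(population, file.path(out_dir, "population.csv"))
  truth <- list(
    timeline = lapply(seq_len(nrow(model$timeline)), function(i) list(
      name = model$timeline$event[i], date = format(model$timeline$date[i]),
      immediate = model$timeline$immediate[i],
      sustained = model$timeline$sustained[i]
    )),
    coefficients = lapply(model$coefficients, as.list),
    noise = model$noise, sd = model$sd, ar1 = model$ar1, seed = seed,
    months = range(months), split = split, suppress_below = suppress_below
  )
  truth_path <- file.path(out_dir, "truth.yaml")
  yaml::write_yaml(truth, truth_path)
  invisible(c(paths, list(population = pop_path, truth = truth_path)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on WONDER-dialect inputs: parse and merge the
#' final/provisional pair, assemble monthly rate series with interpolated
#' populations, fit the segmented regression per region (optionally the
#' gender-interaction model), project the no-COVID counterfactual, compute
#' excess and cumulative excess deaths, run the Poisson bootstrap, aggregate
#' nationally, and write coefficient tables, diagnostics, excess series, CI
#' tables, figures, and a run manifest to the output directory.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   `final`, `provisional` (WONDER export paths), `population` (annual
#'   anchors CSV), `cutoff` (`"YYYY-MM"` merge cutoff), and optionally
#'   `timeline` (YAML path), `months` (c(first, last) indices, default
#'   c(1, 286)), `model` (`"foundational"` or `"gender"`), `regions`,
#'   `bootstrap_B` (default 1000), `seed`, `out` (output directory),
#'   `plots` (default TRUE).
#' @return invisible list with per-region fits, excess series, bootstrap
#'   objects, and the national aggregate.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("final", "provisional", "population", "cutoff", "out", "seed")) {
    if (is.null(config[[key]])) stop("config is missing `", key, "`", call. = FALSE)
  }
  for (key in c("final", "provisional", "population")) {
    if (!file.exists(config[[key]])) {
      stop("input file does not exist: ", config[[key]], call. = FALSE)
    }
  }
  timeline <- if (!is.null(config$timeline)) read_timeline(config$timeline)
              else default_timeline()
  months <- if (!is.null(config$months)) seq(config$months[1], config$months[2])
            else 1:286
  model_variant <- if (!is.null(config$model)) config$model else "foundational"
  B <- if (!is.null(config$bootstrap_B)) config$bootstrap_B else 1000
  out_dir <- config$out
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  message("[ingest] parsing and merging WONDER exports")
  final <- parse_wonder_export(config$final, "final")
  prov <- parse_wonder_export(config$provisional, "provisional")
  counts <- merge_final_provisional(final, prov, config$cutoff)
  if (model_variant == "foundational" && length(unique(counts$gender)) > 1) {
    counts <- aggregate_over_gender(counts)
  }
  population <- read_population_csv(config$population)
  rates <- build_rate_series(counts, population)
  rates <- rates[rates$t %in% months, , drop = FALSE]
  regions <- if (!is.null(config$regions)) config$regions
             else sort(unique(rates$region))
  covid_start <- timeline$index[timeline$event == "COVID"]

  fits <- list(); excess <- list(); boots <- list()
  for (rg in regions) {
    message("[fit] region ", rg)
    sr <- rates[rates$region == rg, , drop = FALSE]
    sr <- sr[order(sr$gender, sr$t), , drop = FALSE]
    if (model_variant == "gender") {
      X <- build_interaction_design(sr$t, sr$gender, timeline)
    } else {
      X <- build_design_matrix(sr$t, timeline)
    }
    fit <- fit_its(X, sr$rate)
    fits[[rg]] <- fit
    readr::write_csv(coefficient_table(fit),
                     file.path(out_dir, paste0("coefficients_", rg, ".csv")))
    diag <- compute_diagnostics(fit)
    readr::write_csv(diag$influence,
                     file.path(out_dir, paste0("diagnostics_", rg, ".csv")))

    post <- sr$t >= covid_start
    Xcf <- counterfactual_design(unclass(X)[post, , drop = FALSE])
    cf <- counterfactual_predict(fit, Xcf)
    ex <- excess_series(sr$t[post], sr$rate[post], cf, sr$population[post])
    ex <- dplyr::mutate(ex, region = rg, .before = 1)
    excess[[rg]] <- ex
    readr::write_csv(ex, file.path(out_dir, paste0("excess_", rg, ".csv")))

    message("[bootstrap] region ", rg, " (B = ", B, ")")
    boot_series <- if (model_variant == "gender") {
      agg <- dplyr::summarise(dplyr::group_by(sr, .data$t),
                              deaths = sum(.data$deaths),
                              population = sum(.data$population),
                              .groups = "drop")
      agg
    } else sr
    boots[[rg]] <- bootstrap_cumulative_excess(
      boot_series, timeline, B = B,
      seed = as.integer(config$seed) + match(rg, regions), start = covid_start
    )
    readr::write_csv(boots[[rg]]$ci,
                     file.path(out_dir, paste0("bootstrap_ci_", rg, ".csv")))
    if (!identical(config$plots, FALSE) && model_variant != "gender") {
      plot_region_fit(sr, fit, timeline, covid_start,
                      file.path(out_dir, paste0("fit_", rg, ".png")), rg)
    }
  }

  national <- national_bootstrap(boots)
  readr::write_csv(national$ci, file.path(out_dir, "bootstrap_ci_national.csv"))
  nat_excess <- aggregate_national(excess)
  readr::write_csv(nat_excess, file.path(out_dir, "cumulative_excess_national.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("opioidits")),
    seed = config$seed, model = model_variant, bootstrap_B = B,
    cutoff = config$cutoff, months = range(months), regions = regions,
    interpolation = "days", standard_errors = "classical",
    quantile_type = 7,
    timeline = lapply(seq_len(nrow(timeline)), function(i) list(
      name = timeline$event[i], date = format(timeline$date[i]),
      index = timeline$index[i]
    ))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(fits = fits, excess = excess, bootstrap = boots,
                 national = national, rates = rates))
}

plot_region_fit <- function(sr, fit, timeline, covid_start, path, region) {
  pred <- predict_with_intervals(fit)
  df <- tibble::tibble(date = sr$date, rate = sr$rate, fit = pred$fit,
                       ci.lower = pred$ci.lower, ci.upper = pred$ci.upper,
                       pi.lower = pred$pi.lower, pi.upper = pred$pi.upper)
  Xcf <- counterfactual_design(fit$design)
  cf <- counterfactual_predict(fit, Xcf)
  post <- sr$t >= covid_start
  cfdf <- tibble::tibble(date = sr$date[post], fit = cf$fit[post],
                         pi.lower = cf$pi.lower[post],
                         pi.upper = cf$pi.upper[post])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pi.lower,
                                      ymax = .data$pi.upper),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci.lower,
                                      ymax = .data$ci.upper),
                         fill = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$rate), size = 0.6,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), color = "red") +
    ggplot2::geom_ribbon(data = cfdf,
                         ggplot2::aes(ymin = .data$pi.lower,
                                      ymax = .data$pi.upper),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(data = cfdf, ggplot2::aes(y = .data$fit),
                       color = "steelblue") +
    ggplot2::geom_vline(xintercept = timeline$date, linetype = "dashed",
                        color = "grey40") +
    ggplot2::labs(title = paste0(region, ": monthly opioid-related death rate"),
                  x = NULL, y = "deaths per 100,000") +
    ggplot2::theme_minimal()
  tryCatch(ggplot2::ggsave(path, p, width = 9, height = 5, dpi = 120),
           error = function(e) warning("could not write figure: ",
                                       conditionMessage(e), call. = FALSE))
  invisible(path)
}
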