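#' Counterfactual projection: the trajectory without COVID-19
#'
#' Evaluates the fitted model on design rows in which the COVID-19 level and
#' slope terms and the CHW slope term are zero, i.e. the linear predictor
#' retains only the pre-pandemic structure (baseline trend, heroin, fentanyl,
#' PHE terms). The rows must already have those columns zeroed (use
#' [counterfactual_design()]); nonzero entries raise an error, guarding
#' against accidental leakage of pandemic terms into the projection.
#'
#' @param fit an [fit_its()] result.
#' @param design design rows with the counterfactual events' columns zeroed.
#' @param events event names that must be zeroed (default COVID and CHW).
#' @param level interval coverage (default 0.95).
#' @return tibble as [predict_with_intervals()]: `fit`, `se.fit`, CI and PI
#'   bounds, where `fit` is the counterfactual rate.
#' @export
counterfactual_predict <- function(fit, design, events = c("COVID", "CHW"),
                                   level = 0.95) {
  X <- as.matrix(design)
  pat <- paste0("^(Male_)?(Indicator|MonthsSince)_(",
                paste(events, collapse = "|"), ")$")
  hit <- grepl(pat, colnames(X))
  if (any(X[, hit] != 0)) {
    stop("counterfactual design rows must have the ",
         paste(events, collapse = "/"),
         " columns zeroed; call counterfactual_design() first", call. = FALSE)
  }
  predict_with_intervals(fit, X, level = level)
}

#' Excess and cumulative excess opioid deaths
#'
#' From aligned observed rates, counterfactual rates, and populations
#' (months from the pandemic onset), computes the excess death rate
#' `r_t = y_t - ytilde_t`, the absolute excess deaths
#' `s_t = r_t * p_t / 100000`, and the running cumulative excess
#' `c_t = sum(s_255..s_t)`. Excess quantities are kept real-valued; rounding
#' is a reporting concern. A prediction interval for the excess rate is
#' attached when the counterfactual carries PI bounds: the counterfactual PI
#' reflected around the observed rate (observed treated as fixed).
#'
#' @param t integer month indices (contiguous, typically 255:286).
#' @param observed observed rates `y_t` (per 100,000).
#' @param counterfactual counterfactual rates `ytilde_t`, or a tibble from
#'   [counterfactual_predict()] (its `fit`/`pi.*` columns are used).
#' @param population interpolated monthly population `p_t`.
#' @return tibble `t`, `observed`, `counterfactual`, `excess_rate`,
#'   `excess_deaths`, `cumulative_excess` (+ `excess_rate_pi_lower/upper`
#'   when available).
#' @export
excess_series <- function(t, observed, counterfactual, population) {
  pi_lo <- pi_hi <- NULL
  if (is.data.frame(counterfactual)) {
    if (all(c("pi.lower", "pi.upper") %in% names(counterfactual))) {
      pi_lo <- counterfactual$pi.lower
      pi_hi <- counterfactual$pi.upper
    }
    counterfactual <- counterfactual$fit
  }
  n <- length(t)
  if (length(observed) != n || length(counterfactual) != n ||
      length(population) != n) {
    stop("t, observed, counterfactual, and population must align month-for-month",
         call. = FALSE)
  }
  if (n > 1 && any(diff(as.integer(t)) != 1L)) {
    stop("months must be contiguous for the cumulative sum", call. = FALSE)
  }
  r <- observed - counterfactual
  s <- r * population / 1e5
  out <- tibble::tibble(
    t = as.integer(t), observed = observed, counterfactual = counterfactual,
    excess_rate = r, excess_deaths = s, cumulative_excess = cumsum(s)
  )
  if (!is.null(pi_lo)) {
    out$excess_rate_pi_lower <- observed - pi_hi
    out$excess_rate_pi_upper <- observed - pi_lo
  }
  out
}

#' Aggregate regional excess series to the national level
#'
#' Elementwise sum of a quantity across the regions, month by month. All
#' regions must be present and aligned on the same months.
#'
#' @param series_list named list of per-region tibbles sharing a `t` column
#'   and the `column` to sum.
#' @param column which column to aggregate (default `"cumulative_excess"`).
#' @param regions required region names (default: the list's own names).
#' @return tibble `t`, `<column>` summed across regions.
#' @export
aggregate_national <- function(series_list, column = "cumulative_excess",
                               regions = names(series_list)) {
  missing_r <- setdiff(regions, names(series_list))
  if (length(missing_r) > 0) {
    stop("missing region(s): ", paste(missing_r, collapse = ", "), call. = FALSE)
  }
  series_list <- series_list[regions]
  t0 <- series_list[[1]]$t
  acc <- numeric(length(t0))
  for (s in series_list) {
    if (!identical(as.integer(s$t), as.integer(t0))) {
      stop("regions are not aligned on the same months", call. = FALSE)
    }
    acc <- acc + s[[column]]
  }
  out <- tibble::tibble(t = as.integer(t0))
  out[[column]] <- acc
  out
}

#' Share of non-COVID excess deaths attributable to opioids
#'
#' Computes `100 * oCED / nCED`, the percentage of non-COVID-19 cumulative
#' excess deaths (nCED) accounted for by model-estimated cumulative excess
#' opioid deaths (oCED). nCED can be given directly (preferred, when a
#' published count exists) or derived as all-cause excess minus COVID-19
#' deaths — supplied either as a count or as the share of all-cause excess
#' attributed to COVID-19.
#'
#' @param oced cumulative excess opioid deaths.
#' @param nced non-COVID excess deaths (if known directly).
#' @param aced all-cause cumulative excess deaths (used when `nced` absent).
#' @param covid_deaths COVID-19 death count to subtract from `aced`.
#' @param covid_share proportion (0--1) of `aced` attributed to COVID-19.
#' @return attribution percentage (vectorized), unrounded; report to one
#'   decimal.
#' @examples
#' round(attribution_percent(5582, nced = 27065), 1) # 20.6
#' @export
attribution_percent <- function(oced, nced = NULL, aced = NULL,
                                covid_deaths = NULL, covid_share = NULL) {
  if (is.null(nced)) {
    if (is.null(aced)) {
      stop("supply `nced`, or `aced` with `covid_deaths` or `covid_share`",
           call. = FALSE)
    }
    nced <- if (!is.null(covid_deaths)) aced - covid_deaths
            else if (!is.null(covid_share)) aced * (1 - covid_share)
            else stop("supply `covid_deaths` or `covid_share` with `aced`",
                      call. = FALSE)
  }
  if (any(nced <= 0)) stop("nCED must be strictly positive", call. = FALSE)
  100 * oced / nced
}
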