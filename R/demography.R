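#' Month-end calendar dates for year-month observations
#'
#' Monthly death counts cover the whole month, so each observation is
#' anchored to the final calendar day of its month (leap-aware): January
#' deaths correspond to January 31, April deaths to April 30, and so on.
#'
#' @param year,month integer vectors (recycled to common length).
#' @return `Date` vector of month-end dates.
#' @examples
#' assign_month_end_dates(2020, 2) # 2020-02-29
#' @export
assign_month_end_dates <- function(year, month) {
  stopifnot(all(month >= 1 & month <= 12))
  first <- as.Date(sprintf("%04d-%02d-01", as.integer(year), as.integer(month)))
  lubridate::ceiling_date(first, "month") - 1
}

#' Interpolate annual July-1 population anchors to arbitrary dates
#'
#' Annual population estimates are anchored to July 1 of their year and
#' interpolated linearly in elapsed calendar days between bracketing anchors
#' (so a July-to-July span is 365 or 366 days as the calendar dictates).
#' Dates before the first anchor take the first anchor's value (backfill);
#' dates after the last anchor take the last anchor's value. A
#' `"month-uniform"` mode interpolates linearly in month counts instead, for
#' sensitivity checks.
#'
#' @param anchors data frame with columns `year` and `population` (one row
#'   per year, a July-1 value).
#' @param target_dates `Date` vector at which population is wanted
#'   (typically month-end dates).
#' @param method `"days"` (default) or `"month-uniform"`.
#' @return numeric vector of interpolated populations, same length as
#'   `target_dates`.
#' @export
interpolate_population <- function(anchors, target_dates,
                                   method = c("days", "month-uniform")) {
  method <- match.arg(method)
  if (nrow(anchors) == 0) stop("no population anchors supplied", call. = FALSE)
  anchors <- anchors[order(anchors$year), , drop = FALSE]
  if (any(anchors$population <= 0)) {
    stop("population anchors must be strictly positive", call. = FALSE)
  }
  anchor_dates <- as.Date(sprintf("%04d-07-01", as.integer(anchors$year)))
  if (nrow(anchors) == 1) {
    return(rep(anchors$population, length(target_dates)))
  }
  if (method == "days") {
    x <- as.numeric(anchor_dates)
    xout <- as.numeric(as.Date(target_dates))
  } else {
    x <- monthly_index(anchor_dates) + (as.integer(format(anchor_dates, "%d")) - 1) / 31
    td <- as.Date(target_dates)
    xout <- monthly_index(td) + (as.integer(format(td, "%d")) - 1) / 31
  }
  stats::approx(x, anchors$population, xout = xout, rule = 2)$y
}

#' Monthly death rate per 100,000 persons
#'
#' @param d death counts (non-negative).
#' @param p population (strictly positive).
#' @return `100000 * d / p`, unrounded.
#' @examples
#' compute_death_rate(100, 1e6) # 10
#' @export
compute_death_rate <- function(d, p) {
  if (any(p <= 0)) stop("population must be strictly positive", call. = FALSE)
  if (any(d < 0)) stop("death counts must be non-negative", call. = FALSE)
  100000 * d / p
}

#' Assemble a monthly rate series from counts and population anchors
#'
#' Joins a per-stratum monthly count table with day-interpolated populations
#' (anchored at month-end dates) and computes the monthly death rate per
#' 100,000. Suppressed (missing) counts propagate as missing rates.
#'
#' @param counts tibble with columns `region`, `gender`, `year`, `month`,
#'   `count` (NA allowed for suppressed cells).
#' @param population tibble with columns `region`, `gender`, `year`,
#'   `population` (annual July-1 anchors).
#' @param method interpolation mode passed to [interpolate_population()].
#' @return tibble with `region`, `gender`, `t`, `date`, `deaths`,
#'   `population`, `rate`, ordered by stratum then month.
#' @export
build_rate_series <- function(counts, population, method = "days") {
  stopifnot(all(c("region", "gender", "year", "month", "count") %in% names(counts)))
  stopifnot(all(c("region", "gender", "year", "population") %in% names(population)))
  counts <- dplyr::mutate(
    counts,
    date = assign_month_end_dates(.data$year, .data$month),
    t = monthly_index(.data$date)
  )
  out <- dplyr::group_modify(
    dplyr::group_by(counts, .data$region, .data$gender),
    function(df, key) {
      anch <- population[population$region == key$region &
                           population$gender == key$gender, , drop = FALSE]
      if (nrow(anch) == 0) {
        stop("no population anchors for stratum ", key$region, " / ",
             key$gender, call. = FALSE)
      }
      df$population <- interpolate_population(anch, df$date, method = method)
      df
    }
  )
  out <- dplyr::ungroup(out)
  out$rate <- ifelse(is.na(out$count), NA_real_,
                     compute_death_rate(ifelse(is.na(out$count), 0, out$count),
                                        out$population))
  dplyr::arrange(
    dplyr::select(out, "region", "gender", "t", "date",
                  deaths = "count", "population", "rate"),
    .data$region, .data$gender, .data$t
  )
}
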