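#' Month index relative to January 1999
#'
#' Converts calendar dates (or `"YYYY-MM"` strings) to the month-index
#' convention used throughout the package: January 1999 is month 1, and each
#' subsequent calendar month increments the index by one. The day of month is
#' ignored, so an intervention dated mid-month carries the index of the month
#' it falls in.
#'
#' @param date a `Date` vector, or a character vector in `"YYYY-MM"` or
#'   `"YYYY-MM-DD"` form.
#' @return integer vector of month indices (Jan 1999 = 1).
#' @examples
#' monthly_index(as.Date("2020-03-13")) # 255
#' monthly_index("2010-01")             # 133
#' @export
monthly_index <- function(date) {
  if (is.character(date)) {
    date <- ifelse(grepl("^\\d{4}-\\d{2}$", date), paste0(date, "-01"), date)
    date <- as.Date(date)
  }
  if (!inherits(date, "Date")) {
    stop("`date` must be a Date or 'YYYY-MM' character vector", call. = FALSE)
  }
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  if (any(y < 1999L)) {
    stop("dates before 1999-01-01 are outside the month-index origin", call. = FALSE)
  }
  (y - 1999L) * 12L + m
}

#' Inverse of [monthly_index()]: first day of the indexed month
#' @param t integer month index (Jan 1999 = 1).
#' @return `Date` vector (first of month).
#' @export
index_to_date <- function(t) {
  stopifnot(all(t >= 1L))
  y <- 1999L + (t - 1L) %/% 12L
  m <- (t - 1L) %% 12L + 1L
  as.Date(sprintf("%04d-%02d-01", y, m))
}

#' Intervention timeline for the U.S. opioid epidemic
#'
#' Builds the ordered table of intervention events that define the segments of
#' the ITS model. Each event carries a calendar date, its month index, and
#' flags saying whether it contributes an immediate (level-shift) effect, a
#' sustained (slope-change) effect, or both. The default timeline encodes the
#' epidemic's defining events: the rise of heroin (January 2010), the
#' dominance of fentanyl and other synthetic opioids (January 2013), the
#' declaration of the opioid public health emergency (PHE, 26 October 2017),
#' the COVID-19 national emergency (13 March 2020), and the CDC community
#' health worker (CHW) funding announcement (25 March 2021). PHE and CHW enter
#' the model with sustained effects only.
#'
#' @param events character vector of event names.
#' @param dates `Date` (or parseable character) vector of event dates.
#' @param immediate,sustained logical vectors: which effect(s) each event has.
#' @return a tibble of class `its_timeline` with columns `event`, `date`,
#'   `index`, `immediate`, `sustained`, sorted by date.
#' @export
intervention_timeline <- function(events, dates, immediate, sustained) {
  dates <- as.Date(dates)
  stopifnot(
    length(events) == length(dates),
    length(immediate) == length(dates),
    length(sustained) == length(dates)
  )
  if (anyDuplicated(events)) stop("event names must be unique", call. = FALSE)
  if (any(!immediate & !sustained)) {
    stop("every event must have at least one effect (immediate or sustained)",
         call. = FALSE)
  }
  tl <- tibble::tibble(
    event = as.character(events),
    date = dates,
    index = monthly_index(dates),
    immediate = as.logical(immediate),
    sustained = as.logical(sustained)
  )
  tl <- dplyr::arrange(tl, .data$date)
  class(tl) <- c("its_timeline", class(tl))
  tl
}

#' @rdname intervention_timeline
#' @export
default_timeline <- function() {
  intervention_timeline(
    events = c("Heroin", "Fentanyl", "PHE", "COVID", "CHW"),
    dates = as.Date(c("2010-01-01", "2013-01-01", "2017-10-26",
                      "2020-03-13", "2021-03-25")),
    immediate = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    sustained = c(TRUE, TRUE, TRUE, TRUE, TRUE)
  )
}

#' Read / write a timeline as YAML
#'
#' The YAML schema is a list of `{name, date, immediate, sustained}` entries,
#' so alternative timelines (e.g. region-specific interventions) can be
#' expressed without code changes.
#'
#' @param path file path.
#' @return [read_timeline()] returns an `its_timeline`;
#'   [write_timeline()] returns `path` invisibly.
#' @export
read_timeline <- function(path) {
  spec <- yaml::read_yaml(path)
  intervention_timeline(
    events = vapply(spec, `[[`, "", "name"),
    dates = as.Date(vapply(spec, `[[`, "", "date")),
    immediate = vapply(spec, `[[`, NA, "immediate"),
    sustained = vapply(spec, `[[`, NA, "sustained")
  )
}

#' @rdname read_timeline
#' @param timeline an `its_timeline`.
#' @export
write_timeline <- function(timeline, path) {
  entries <- lapply(seq_len(nrow(timeline)), function(i) {
    list(
      name = timeline$event[i],
      date = format(timeline$date[i]),
      immediate = timeline$immediate[i],
      sustained = timeline$sustained[i]
    )
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
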