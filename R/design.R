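#' Intervention indicators and elapsed times at given months
#'
#' For each event E in the timeline, computes the step indicator
#' `I_t(E) = 1{t >= index(E)}` and the elapsed time
#' `P_t(E) = max(0, t - (index(E) - 1))`, so that P equals 1 in the event
#' month itself and 0 before it. Indicators and elapsed times are returned
#' for every event, including events whose immediate effect is not part of
#' the regression design, so the full set can be inspected.
#'
#' @param t integer vector of month indices (Jan 1999 = 1).
#' @param timeline an [intervention_timeline()].
#' @return tibble with column `t` plus `Indicator_<event>` and
#'   `MonthsSince_<event>` columns for every event.
#' @export
build_intervention_variables <- function(t, timeline = default_timeline()) {
  stopifnot(is.numeric(t), all(t >= 1))
  out <- tibble::tibble(t = as.integer(t))
  for (i in seq_len(nrow(timeline))) {
    idx <- timeline$index[i]
    ev <- timeline$event[i]
    out[[paste0("Indicator_", ev)]] <- as.integer(t >= idx)
    out[[paste0("MonthsSince_", ev)]] <- pmax(0L, as.integer(t) - (idx - 1L))
  }
  out
}

design_column_names <- function(timeline) {
  cols <- c("Intercept", "Month")
  for (i in seq_len(nrow(timeline))) {
    ev <- timeline$event[i]
    if (timeline$immediate[i]) cols <- c(cols, paste0("Indicator_", ev))
    if (timeline$sustained[i]) cols <- c(cols, paste0("MonthsSince_", ev))
  }
  cols
}

#' Build the ITS regression design matrix
#'
#' Constructs the regressor matrix of the multi-intervention segmented
#' regression: an intercept, the linear month term, and, for each timeline
#' event, an indicator column if the event has an immediate effect and a
#' months-elapsed column if it has a sustained effect. Under the default
#' timeline this yields ten columns, in order: Intercept, Month,
#' Indicator_Heroin, MonthsSince_Heroin, Indicator_Fentanyl,
#' MonthsSince_Fentanyl, MonthsSince_PHE, Indicator_COVID, MonthsSince_COVID,
#' MonthsSince_CHW. PHE and CHW contribute no indicator column (sustained
#' effects only).
#'
#' @param t integer vector of contiguous month indices.
#' @param timeline an [intervention_timeline()].
#' @return numeric matrix with one row per month; attributes `t` and
#'   `timeline` carry the inputs. Class `its_design`.
#' @export
build_design_matrix <- function(t, timeline = default_timeline()) {
  t <- as.integer(t)
  if (length(t) > 1 && any(diff(t) != 1L)) {
    stop("month indices must be contiguous (gap found in `t`)", call. = FALSE)
  }
  iv <- build_intervention_variables(t, timeline)
  cols <- design_column_names(timeline)
  X <- matrix(0, nrow = length(t), ncol = length(cols),
              dimnames = list(NULL, cols))
  X[, "Intercept"] <- 1
  X[, "Month"] <- t
  for (nm in setdiff(cols, c("Intercept", "Month"))) X[, nm] <- iv[[nm]]
  # warn on short segments: ITS wants >= 8 observations either side of a cut
  for (i in seq_len(nrow(timeline))) {
    before <- sum(t < timeline$index[i])
    after <- sum(t >= timeline$index[i])
    if (before > 0 && after > 0 && (before < 8 || after < 8)) {
      warning(sprintf("fewer than 8 observations on one side of event '%s'",
                      timeline$event[i]), call. = FALSE)
    }
  }
  structure(X, t = t, timeline = timeline, class = c("its_design", "matrix", "array"))
}

#' Build the gender-interaction design matrix
#'
#' Stacks two strata (female as the baseline, male as deviation) and fully
#' interacts every ITS regressor with the male indicator. The female rows
#' carry zeros in every interaction column, so the baseline coefficient block
#' is the female model and the interaction block holds male deviations from
#' it. Both strata must cover exactly the same months.
#'
#' @param t integer vector of contiguous month indices (shared by both strata).
#' @param gender character/factor vector, one entry per stacked row, with
#'   levels `"Female"` and `"Male"`; alternatively omit and the function
#'   stacks female rows then male rows over `t`.
#' @param timeline an [intervention_timeline()].
#' @return matrix with twice the base columns; interaction columns are
#'   prefixed `Male_`. Attribute `gender` records the row coding.
#' @export
build_interaction_design <- function(t, gender = NULL, timeline = default_timeline()) {
  t <- as.integer(t)
  if (is.null(gender)) {
    gender <- rep(c("Female", "Male"), each = length(t))
    t <- rep(t, 2L)
  }
  gender <- as.character(gender)
  if (!all(gender %in% c("Female", "Male"))) {
    stop("gender must be coded 'Female' / 'Male'", call. = FALSE)
  }
  tf <- sort(unique(t[gender == "Female"]))
  tm <- sort(unique(t[gender == "Male"]))
  if (!identical(tf, tm)) {
    stop("female and male strata must cover identical months", call. = FALSE)
  }
  base <- build_design_matrix_rows(t, timeline)
  male <- as.numeric(gender == "Male")
  inter <- base * male
  colnames(inter) <- paste0("Male_", colnames(base))
  X <- cbind(base, inter)
  structure(X, t = t, timeline = timeline, gender = gender,
            class = c("its_design", "matrix", "array"))
}

# design rows without the contiguity requirement (used for stacked strata and
# for prediction grids)
build_design_matrix_rows <- function(t, timeline = default_timeline()) {
  iv <- build_intervention_variables(as.integer(t), timeline)
  cols <- design_column_names(timeline)
  X <- matrix(0, nrow = length(t), ncol = length(cols),
              dimnames = list(NULL, cols))
  X[, "Intercept"] <- 1
  X[, "Month"] <- as.integer(t)
  for (nm in setdiff(cols, c("Intercept", "Month"))) X[, nm] <- iv[[nm]]
  X
}

#' Zero out selected interventions in a design (counterfactual rows)
#'
#' Returns a copy of the design rows with every column belonging to the named
#' events set to zero — the design under which the fitted model projects the
#' trajectory that would have been observed had those events not occurred.
#' With the defaults this removes the COVID-19 level and slope terms and the
#' CHW slope term, leaving the pre-pandemic structure.
#'
#' @param design a design matrix from [build_design_matrix()] (or plain
#'   matrix with the same column names).
#' @param events character vector of event names to remove.
#' @return matrix of the same shape with the named events' columns zeroed.
#' @export
counterfactual_design <- function(design, events = c("COVID", "CHW")) {
  X <- design
  pat <- paste0("^(Male_)?(Indicator|MonthsSince)_(",
                paste(events, collapse = "|"), ")$")
  hit <- grepl(pat, colnames(X))
  if (!any(hit)) {
    stop("no design columns match the events to zero: ",
         paste(events, collapse = ", "), call. = FALSE)
  }
  X[, hit] <- 0
  X
}
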