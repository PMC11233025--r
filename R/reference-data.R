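#' Published reference estimates bundled with the package
#'
#' Small plain-text tables of published regional estimates for the
#' 2020--2022 pandemic window, shipped for worked examples, arithmetic
#' cross-checks, and as defaults for the synthetic-data generator:
#'
#' * `regional_its_coefficients()` — fitted ITS coefficients of the
#'   foundational model per Census Region (deaths per 100,000 for levels,
#'   per 100,000 per month for slopes).
#' * `regional_cumulative_excess()` — regional cumulative excess
#'   opioid-related deaths, March 2020 to October 2022, with 95% bootstrap
#'   interval bounds.
#' * `attribution_inputs()` — literature all-cause cumulative excess deaths
#'   (aCED), the share attributed to COVID-19, the implied non-COVID excess
#'   deaths (nCED), and model cumulative excess opioid deaths (oCED) per
#'   reporting period.
#'
#' @return a tibble.
#' @name reference_data
NULL

ref_csv <- function(name) {
  readr::read_csv(system.file("extdata", name, package = "opioidits",
                              mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_data
#' @export
regional_its_coefficients <- function() ref_csv("regional_its_coefficients.csv")

#' @rdname reference_data
#' @export
regional_cumulative_excess <- function() ref_csv("regional_cumulative_excess.csv")

#' @rdname reference_data
#' @export
attribution_inputs <- function() ref_csv("attribution_inputs.csv")
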