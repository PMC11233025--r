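#' ICD-10 inclusion rule for opioid-related deaths
#'
#' A death certificate counts as opioid-related when its underlying cause is
#' a drug-poisoning code — X40–X44 (accidental), X60–X64 (intentional
#' self-poisoning), X85 (assault), or Y10–Y14 (undetermined intent) — AND at
#' least one contributing cause is an opioid T code: T40.0 (opium), T40.1
#' (heroin), T40.2 (other opioids), T40.3 (methadone), T40.4 (synthetic
#' narcotics), or T40.6 (other/unspecified narcotics). Codes are matched
#' exactly after normalization (dots stripped, upper-cased); ranges are
#' expanded to explicit lists so that e.g. T40.5 (cocaine) can never match by
#' prefix.
#'
#' @return list with character vectors `underlying` and `contributing`
#'   (normalized codes), class `opioid_code_rule`.
#' @export
opioid_code_rule <- function() {
  structure(
    list(
      underlying = c(paste0("X4", 0:4), paste0("X6", 0:4), "X85",
                     paste0("Y1", 0:4)),
      contributing = paste0("T40", c(0:4, 6))
    ),
    class = "opioid_code_rule"
  )
}

normalize_icd10 <- function(code) {
  out <- toupper(gsub("\\.", "", trimws(code)))
  bad <- !grepl("^[A-Z][0-9]{2}[0-9A-Z]?$", out) & nzchar(out)
  if (any(bad)) {
    stop("syntactically invalid ICD-10 code(s): ",
         paste(unique(code[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Apply the opioid ICD-10 rule to record-level certificates
#'
#' A pure predicate over certificates: a record is kept iff its underlying
#' cause is in the rule's underlying set and at least one contributing cause
#' is in the contributing set. Multiple qualifying T codes on one certificate
#' count the death once. `filter_opioid_deaths()` returns the kept records;
#' `opioid_filter_matches()` returns the logical keep vector so callers can
#' recover the kept/dropped partition.
#'
#' @param certificates tibble with columns `underlying` (one code per
#'   record) and `contributing` (list-column of character vectors, possibly
#'   empty).
#' @param rule an [opioid_code_rule()].
#' @return filtered tibble ([filter_opioid_deaths()]) or logical vector
#'   ([opioid_filter_matches()]).
#' @export
filter_opioid_deaths <- function(certificates, rule = opioid_code_rule()) {
  certificates[opioid_filter_matches(certificates, rule), , drop = FALSE]
}

#' @rdname filter_opioid_deaths
#' @export
opioid_filter_matches <- function(certificates, rule = opioid_code_rule()) {
  stopifnot(all(c("underlying", "contributing") %in% names(certificates)))
  und <- normalize_icd10(certificates$underlying)
  und_ok <- und %in% rule$underlying
  con_ok <- vapply(certificates$contributing, function(cc) {
    if (length(cc) == 0) return(FALSE)
    any(normalize_icd10(cc) %in% rule$contributing)
  }, logical(1))
  und_ok & con_ok
}

wonder_required_cols <- c("Census Region", "Gender", "Year", "Month", "Deaths")

#' Parse a WONDER-dialect mortality export
#'
#' Reads a tab-separated export of monthly death counts by Census Region and
#' gender. The format has a header row, one data row per
#' Region x Gender x Year x Month, the literal token `"Suppressed"` where a
#' cell count below the suppression cutoff was withheld, and a trailing
#' Notes block of lines prefixed `"---"` which is skipped. "Total" rows are
#' excluded.
#'
#' @param path file path.
#' @param provenance label recorded in the output (`"final"` or
#'   `"provisional"`).
#' @return tibble with columns `region`, `gender`, `year`, `month`,
#'   `count` (integer, `NA` where suppressed), `suppressed` (logical),
#'   `provenance`.
#' @export
parse_wonder_export <- function(path, provenance = "final") {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^---", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(empty_count_table(provenance))
  }
  tab <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(wonder_required_cols, names(tab))
  if (length(missing_cols) > 0) {
    stop("malformed WONDER header; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tab[!grepl("^\\s*Total\\s*$", tab$`Census Region`), , drop = FALSE]
  if (nrow(tab) == 0) return(empty_count_table(provenance))
  suppressed <- tab$Deaths == "Suppressed"
  count <- suppressed
  count <- suppressWarnings(as.integer(ifelse(suppressed, NA, tab$Deaths)))
  bad <- !suppressed & is.na(count)
  if (any(bad)) {
    stop("non-numeric death count: ", tab$Deaths[which(bad)[1]], call. = FALSE)
  }
  if (any(count < 0, na.rm = TRUE)) {
    stop("negative death count in export", call. = FALSE)
  }
  tibble::tibble(
    region = tab$`Census Region`,
    gender = tab$Gender,
    year = as.integer(tab$Year),
    month = as.integer(tab$Month),
    count = count,
    suppressed = suppressed,
    provenance = provenance
  )
}

empty_count_table <- function(provenance = character(0)) {
  tibble::tibble(
    region = character(0), gender = character(0), year = integer(0),
    month = integer(0), count = integer(0), suppressed = logical(0),
    provenance = if (length(provenance)) character(0) else character(0)
  )
}

#' Merge final and provisional monthly count tables
#'
#' The final series is authoritative for months at or before the cutoff; the
#' provisional series supplies months after it. Cells present only in the
#' provisional table before the cutoff are dropped (final is authoritative
#' over its window).
#'
#' @param final,provisional tables from [parse_wonder_export()].
#' @param cutoff `"YYYY-MM"` (or Date): last month taken from the final
#'   table.
#' @return merged table, one row per stratum-month, sorted.
#' @export
merge_final_provisional <- function(final, provisional, cutoff) {
  if (missing(cutoff) || is.null(cutoff)) {
    stop("a final/provisional cutoff month is required", call. = FALSE)
  }
  cut_idx <- monthly_index(cutoff)
  ym <- function(tab) (tab$year - 1999L) * 12L + tab$month
  final$provenance <- "final"
  provisional$provenance <- "provisional"
  out <- dplyr::bind_rows(
    final[ym(final) <= cut_idx, , drop = FALSE],
    provisional[ym(provisional) > cut_idx, , drop = FALSE]
  )
  dup <- duplicated(out[, c("region", "gender", "year", "month")])
  if (any(dup)) stop("duplicate stratum-months within one provenance window",
                     call. = FALSE)
  dplyr::arrange(out, .data$region, .data$gender, .data$year, .data$month)
}

#' Aggregate gender strata to the region level
#'
#' Region-month counts are the sum over the gender strata. Suppressed
#' (missing) cells make the sum undefined and raise an error unless the
#' caller opts into treating missing as zero. Each region-month must carry
#' every gender stratum present in the table.
#'
#' @param table a monthly count table.
#' @param missing_as_zero if `TRUE`, suppressed cells contribute 0.
#' @return count table with `gender = "All"`.
#' @export
aggregate_over_gender <- function(table, missing_as_zero = FALSE) {
  genders <- sort(unique(table$gender))
  grp <- dplyr::group_by(table, .data$region, .data$year, .data$month)
  out <- dplyr::summarise(
    grp,
    .present = paste(sort(.data$gender), collapse = "|"),
    .any_na = any(is.na(.data$count)),
    count = if (missing_as_zero) sum(.data$count, na.rm = TRUE)
            else sum(.data$count),
    .groups = "drop"
  )
  incomplete <- out$.present != paste(genders, collapse = "|")
  if (any(incomplete)) {
    i <- which(incomplete)[1]
    have <- strsplit(out$.present[i], "\\|")[[1]]
    stop(sprintf("missing gender stratum '%s' for %s %d-%02d",
                 setdiff(genders, have)[1], out$region[i], out$year[i],
                 out$month[i]), call. = FALSE)
  }
  if (!missing_as_zero && any(out$.any_na)) {
    i <- which(out$.any_na)[1]
    stop(sprintf("suppressed cell in gender sum for %s %d-%02d (set missing_as_zero = TRUE to override)",
                 out$region[i], out$year[i], out$month[i]), call. = FALSE)
  }
  tibble::tibble(
    region = out$region, gender = "All", year = out$year, month = out$month,
    count = as.integer(out$count),
    suppressed = FALSE, provenance = "aggregated"
  )
}

#' Write a normalized monthly count table as CSV
#' @param table count table.
#' @param path output path.
#' @export
write_count_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}
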