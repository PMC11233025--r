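test_that("WONDER exports parse, skipping notes and flagging suppression", {
  path <- write_wonder_text(c(
    "South\tFemale\t1999\t01\t57",
    "South\tMale\t1999\t01\tSuppressed",
    "Total\t\t\t\t999"
  ))
  tab <- parse_wonder_export(path)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$count[tab$gender == "Female"], 57L)
  expect_true(is.na(tab$count[tab$gender == "Male"]))
  expect_true(tab$suppressed[tab$gender == "Male"])
  expect_false(tab$suppressed[tab$gender == "Female"])
})

test_that("degenerate and malformed exports are handled", {
  notes_only <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("---", "--- Only notes here"), notes_only)
  expect_identical(nrow(parse_wonder_export(notes_only)), 0L)

  bad_header <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Region\tGender\tYear\tMonth\tDeaths",
               "South\tFemale\t1999\t01\t5"), bad_header)
  expect_error(parse_wonder_export(bad_header), "Census Region")

  negative <- write_wonder_text("South\tFemale\t1999\t01\t-3")
  expect_error(parse_wonder_export(negative), "negative")
})

test_that("final data wins at or before the cutoff, provisional after", {
  final <- tibble::tibble(
    region = "South", gender = "All",
    year = c(2020L, 2020L), month = c(11L, 12L),
    count = c(100L, 110L), suppressed = FALSE, provenance = "final"
  )
  prov <- tibble::tibble(
    region = "South", gender = "All",
    year = c(2020L, 2021L, 2021L), month = c(12L, 1L, 2L),
    count = c(999L, 120L, 130L), suppressed = FALSE, provenance = "provisional"
  )
  merged <- merge_final_provisional(final, prov, cutoff = "2020-12")
  expect_identical(nrow(merged), 4L)
  dec <- merged[merged$year == 2020 & merged$month == 12, ]
  expect_identical(dec$count, 110L)       # final is authoritative
  expect_identical(dec$provenance, "final")
  expect_identical(merged$count[merged$year == 2021], c(120L, 130L))
  expect_error(merge_final_provisional(final, prov), "cutoff")
  # idempotence: merging a table with itself reproduces it
  self <- merge_final_provisional(final, final, cutoff = "2020-12")
  expect_identical(self$count, final$count)
  # provisional-only cell before the cutoff is dropped
  early_prov <- dplyr::mutate(prov, year = 2019L)
  m2 <- merge_final_provisional(final, early_prov, cutoff = "2020-12")
  expect_false(any(m2$year == 2019))
})

test_that("the ICD-10 opioid rule keeps exactly the qualifying certificates", {
  certs <- tibble::tibble(
    underlying = c("X42", "X42", "W34", "Y12", "X85", "X44", "X60"),
    contributing = list(
      c("T40.1"),           # heroin with accidental poisoning: kept
      c("T51.0"),           # ethanol only: dropped
      c("T40.2"),           # qualifying T but wrong underlying: dropped
      c("T40.4", "T40.6"),  # synthetic narcotics, undetermined intent: kept
      character(0),         # no contributing causes: dropped
      c("T40.5"),           # cocaine must NOT match by prefix: dropped
      c("T42.4", "T40.3")   # methadone among others: kept once
    )
  )
  keep <- opioid_filter_matches(certs)
  expect_identical(keep, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  kept <- filter_opioid_deaths(certs)
  expect_identical(nrow(kept), 3L)
  # pure predicate: idempotent and order-independent
  expect_identical(opioid_filter_matches(kept), rep(TRUE, 3))
  perm <- c(4, 2, 7, 1, 3, 6, 5)
  expect_identical(opioid_filter_matches(certs[perm, ]), keep[perm])
  # kept + dropped partitions the input
  expect_identical(sum(keep) + sum(!keep), nrow(certs))
  expect_error(
    opioid_filter_matches(tibble::tibble(underlying = "4X2",
                                         contributing = list("T40.1"))),
    "invalid"
  )
})

test_that("gender aggregation sums counts and fails loudly on gaps", {
  tab <- tibble::tibble(
    region = "South", gender = c("Female", "Male"),
    year = 1999L, month = 1L, count = c(30L, 70L),
    suppressed = FALSE, provenance = "final"
  )
  agg <- aggregate_over_gender(tab)
  expect_identical(agg$count, 100L)
  expect_identical(agg$gender, "All")

  supp <- tab
  supp$count[1] <- NA
  expect_error(aggregate_over_gender(supp), "uppressed")
  expect_identical(aggregate_over_gender(supp, missing_as_zero = TRUE)$count, 70L)

  missing_stratum <- tab[tab$gender == "Male", ]
  both <- dplyr::bind_rows(tab, dplyr::mutate(missing_stratum, region = "West"))
  expect_error(aggregate_over_gender(both), "Female")
})

test_that("count tables round-trip through the CSV writer", {
  tab <- tibble::tibble(
    region = "South", gender = "All", year = 1999L, month = 1:3,
    count = c(10L, NA, 30L), suppressed = c(FALSE, TRUE, FALSE),
    provenance = "final"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_count_table(tab, path)
  back <- readr::read_csv(path, col_types = "cciiilc", progress = FALSE)
  expect_equal(as.data.frame(back)$count, tab$count)
})
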