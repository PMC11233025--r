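# Small synthetic scaffolding shared across test files.

# A two-stratum (one region, two genders) truth with hand-set coefficients.
two_gender_model <- function(beta_f, beta_m, noise = "gaussian", sd = 0.05) {
  strata <- tibble::tibble(region = "East", gender = c("Female", "Male"))
  true_model(default_timeline(),
             list("East/Female" = beta_f, "East/Male" = beta_m),
             strata, noise = noise, sd = sd)
}

flat_population <- function(strata, size = 1e7, years = 1999:2023) {
  generate_population_table(strata, years, base_sizes = size)
}

# A gentle upward truth that stays positive over 1:286 for any stratum.
gentle_beta <- function() {
  c(Intercept = 0.5, Month = 0.002, Indicator_Heroin = 0.05,
    MonthsSince_Heroin = 0.001, Indicator_Fentanyl = 0.1,
    MonthsSince_Fentanyl = 0.004, MonthsSince_PHE = -0.002,
    Indicator_COVID = 0.4, MonthsSince_COVID = 0.01,
    MonthsSince_CHW = -0.005)
}

south_beta <- function() {
  coefs <- regional_its_coefficients()
  unlist(coefs[coefs$region == "South", -1])
}

# WONDER-dialect fixture text written to a temp file; returns the path.
write_wonder_text <- function(rows, notes = TRUE) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  lines <- "Census Region\tGender\tYear\tMonth\tDeaths"
  lines <- c(lines, rows)
  if (notes) lines <- c(lines, "---", "--- Synthetic note block")
  writeLines(lines, path)
  path
}
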