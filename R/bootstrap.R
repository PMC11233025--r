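#' Poisson resample of monthly death counts
#'
#' Draws independent `d*_t ~ Poisson(d_t)` for every timepoint — step one of
#' the parametric bootstrap. A zero count resamples to zero always.
#'
#' @param counts non-negative integer (or integer-valued) counts.
#' @param seed integer seed (required; draws are reproducible given it).
#' @return integer vector of resampled counts.
#' @export
poisson_resample <- function(counts, seed) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  withr::with_seed(as.integer(seed), stats::rpois(length(counts), counts))
}

#' Parametric bootstrap for cumulative excess deaths
#'
#' Implements the five-step Poisson parametric bootstrap for one stratum's
#' cumulative excess curve. For each of B replicates: (1) resample monthly
#' counts `d*_t ~ Poisson(d_t)` at all timepoints; (2) recompute rates with
#' the original (fixed) populations and refit the segmented regression;
#' (3) project the counterfactual from the refitted coefficients;
#' (4) compute the excess deaths `s*_t` using the resampled observed rates;
#' (5) accumulate `c*_t` over the pandemic months. Per-month confidence
#' bounds are the empirical quantiles of the B replicate curves.
#'
#' @param series tibble with columns `t` (contiguous months), `deaths`,
#'   `population` covering the full analysis range.
#' @param timeline an [intervention_timeline()].
#' @param B number of replicates (default 1000).
#' @param seed integer seed (required).
#' @param start first pandemic month index (default: the COVID event's
#'   index from the timeline).
#' @param levels quantile probabilities for the CI (default 0.025, 0.975).
#' @param qtype empirical quantile estimator, passed to [stats::quantile()]
#'   (default 7, inclusive linear interpolation).
#' @param events counterfactual events to zero (default COVID and CHW).
#' @return object of class `bootstrap_replicates`: list with `replicates`
#'   (months x B matrix of `c*_t`), `ci` tibble (`t`, `point`, `lower`,
#'   `upper`), `B`, `start`, `levels`. `point` is the cumulative excess from
#'   the original (unresampled) fit.
#' @export
bootstrap_cumulative_excess <- function(series, timeline = default_timeline(),
                                        B = 1000, seed, start = NULL,
                                        levels = c(0.025, 0.975), qtype = 7,
                                        events = c("COVID", "CHW")) {
  if (B < 2) stop("B must be at least 2", call. = FALSE)
  if (any(levels <= 0 | levels >= 1)) {
    stop("quantile levels must lie strictly inside (0, 1)", call. = FALSE)
  }
  t <- as.integer(series$t)
  if (any(diff(t) != 1L)) stop("series months must be contiguous", call. = FALSE)
  if (is.null(start)) {
    cov_row <- timeline[timeline$event == "COVID", ]
    if (nrow(cov_row) == 0) stop("no COVID event in timeline; supply `start`",
                                 call. = FALSE)
    start <- cov_row$index
  }
  if (start < min(t) || start > max(t)) {
    stop("`start` must fall inside the series months", call. = FALSE)
  }
  X <- unclass(build_design_matrix(t, timeline))
  post <- t >= start
  Xcf_post <- counterfactual_design(X, events)[post, , drop = FALSE]
  d <- series$deaths
  p <- series$population
  p_post <- p[post]

  one_excess <- function(counts) {
    y <- 100000 * counts / p
    fit <- stats::.lm.fit(X, y)
    if (fit$rank < ncol(X)) stop("rank-deficient design in refit", call. = FALSE)
    beta <- fit$coefficients
    ytilde <- drop(Xcf_post %*% beta)
    r <- y[post] - ytilde
    cumsum(r * p_post / 1e5)
  }

  point <- one_excess(d)
  reps <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(b) {
      dstar <- stats::rpois(length(d), d)
      tryCatch(one_excess(dstar), error = function(e) {
        stop(sprintf("bootstrap replicate %d failed: %s", b, conditionMessage(e)),
             call. = FALSE)
      })
    }, numeric(sum(post)))
  })
  qs <- apply(reps, 1, stats::quantile, probs = levels, type = qtype,
              names = FALSE)
  structure(
    list(
      replicates = reps,
      ci = tibble::tibble(t = t[post], point = point,
                          lower = qs[1, ], upper = qs[2, ]),
      B = B, start = start, levels = levels
    ),
    class = "bootstrap_replicates"
  )
}

#' National bootstrap interval from regional replicate streams
#'
#' Sums replicate cumulative-excess curves across regions replicate-by-
#' replicate (replicate b of the national curve is the sum of each region's
#' own replicate b), then takes empirical quantiles of the summed
#' replicates. The national point estimate is the sum of the regional point
#' estimates.
#'
#' @param replicates_list named list of `bootstrap_replicates`, one per
#'   region.
#' @param levels quantile probabilities (default 0.025, 0.975).
#' @param qtype quantile estimator type (default 7).
#' @return a `bootstrap_replicates` for the national series.
#' @export
national_bootstrap <- function(replicates_list, levels = c(0.025, 0.975),
                               qtype = 7) {
  Bs <- vapply(replicates_list, function(r) r$B, numeric(1))
  if (length(unique(Bs)) != 1) {
    stop("all regions must share the same number of replicates B", call. = FALSE)
  }
  t0 <- replicates_list[[1]]$ci$t
  acc <- matrix(0, nrow = length(t0), ncol = Bs[1])
  point <- numeric(length(t0))
  for (r in replicates_list) {
    if (!identical(as.integer(r$ci$t), as.integer(t0))) {
      stop("regions are not aligned on the same months", call. = FALSE)
    }
    acc <- acc + r$replicates
    point <- point + r$ci$point
  }
  qs <- apply(acc, 1, stats::quantile, probs = levels, type = qtype,
              names = FALSE)
  structure(
    list(
      replicates = acc,
      ci = tibble::tibble(t = as.integer(t0), point = point,
                          lower = qs[1, ], upper = qs[2, ]),
      B = Bs[1], start = replicates_list[[1]]$start, levels = levels
    ),
    class = "bootstrap_replicates"
  )
}

#' @export
print.bootstrap_replicates <- function(x, ...) {
  last <- nrow(x$ci)
  cat(sprintf("Poisson bootstrap: B = %d, months %d..%d\n", x$B,
              x$ci$t[1], x$ci$t[last]))
  cat(sprintf("final-month cumulative excess %.0f (%.1f%% CI %.0f to %.0f)\n",
              x$ci$point[last], 100 * diff(x$levels), x$ci$lower[last],
              x$ci$upper[last]))
  invisible(x)
}
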