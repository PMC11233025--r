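#' Fit the ITS regression by ordinary least squares
#'
#' Fits the segmented regression via `stats::lm()` on a prebuilt design
#' matrix, with classical homoskedastic standard errors and two-sided
#' p-values from the t distribution on the residual degrees of freedom.
#' Coefficients are in deaths per 100,000 persons (levels) or per 100,000 per
#' month (slopes) when the response is a monthly death rate.
#'
#' @param design matrix from [build_design_matrix()] or
#'   [build_interaction_design()] (includes the intercept column).
#' @param y numeric response, one value per design row.
#' @return object of class `its_fit`: a list with the underlying `lm` object
#'   and a tidy `coefficients` tibble (`term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`), plus `sigma`, `df.residual`, `r.squared`,
#'   `adj.r.squared`, `vcov`, `fitted`, `residuals`, and the design.
#' @export
fit_its <- function(design, y) {
  X <- unclass(design)
  attr(X, "t") <- NULL; attr(X, "timeline") <- NULL; attr(X, "gender") <- NULL
  if (nrow(X) <= ncol(X)) {
    stop("need more observations than design columns", call. = FALSE)
  }
  if (length(y) != nrow(X)) stop("response length must match design rows", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  dat <- as.data.frame(X)
  dat$.y <- y
  form <- stats::reformulate(sprintf("`%s`", colnames(X)), response = ".y",
                             intercept = FALSE)
  fit <- stats::lm(form, data = dat)
  names(fit$coefficients) <- colnames(X)
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = ct[, 1],
    std.error = ct[, 2],
    statistic = ct[, 3],
    p.value = ct[, 4]
  )
  V <- sm$sigma^2 * sm$cov.unscaled
  dimnames(V) <- list(colnames(X), colnames(X))
  # r.squared relative to the mean model (design carries its own intercept)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  n <- nrow(X); p <- ncol(X)
  adj <- if (tss > 0) 1 - (1 - r2) * (n - 1) / (n - p) else NA_real_
  structure(
    list(
      lm = fit,
      coefficients = coefs,
      sigma = sm$sigma,
      df.residual = fit$df.residual,
      r.squared = r2,
      adj.r.squared = adj,
      vcov = V,
      fitted = unname(stats::fitted(fit)),
      residuals = unname(stats::residuals(fit)),
      design = X,
      timeline = attr(design, "timeline"),
      t = attr(design, "t"),
      gender = attr(design, "gender")
    ),
    class = "its_fit"
  )
}

#' @export
print.its_fit <- function(x, ...) {
  cat("ITS regression fit:", nrow(x$design), "observations,",
      ncol(x$design), "terms\n")
  cat(sprintf("Residual SE %.5f on %d df; R-squared %.4f (adj. %.4f)\n",
              x$sigma, x$df.residual, x$r.squared, x$adj.r.squared))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @export
coef.its_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.its_fit <- function(object, ...) object$vcov

#' Fitted values with confidence and prediction intervals
#'
#' Evaluates the fitted linear predictor on new design rows and attaches a
#' confidence interval for the mean response and a prediction interval for a
#' new observation. The CI half-width derives from the coefficient
#' covariance; the PI additionally includes the residual variance, so the PI
#' contains the CI pointwise.
#'
#' @param fit an [fit_its()] result.
#' @param design matrix of design rows conformable with the fit.
#' @param level coverage level in (0, 1); default 0.95.
#' @return tibble with `fit`, `se.fit`, `ci.lower`, `ci.upper`, `pi.lower`,
#'   `pi.upper`.
#' @export
predict_with_intervals <- function(fit, design = fit$design, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("`level` must be a single number strictly inside (0, 1)", call. = FALSE)
  }
  X <- as.matrix(design)[, colnames(fit$design), drop = FALSE]
  beta <- coef(fit)
  yhat <- drop(X %*% beta)
  se_fit <- sqrt(rowSums((X %*% fit$vcov) * X))
  se_pred <- sqrt(se_fit^2 + fit$sigma^2)
  tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$df.residual)
  tibble::tibble(
    fit = yhat,
    se.fit = se_fit,
    ci.lower = yhat - tcrit * se_fit,
    ci.upper = yhat + tcrit * se_fit,
    pi.lower = yhat - tcrit * se_pred,
    pi.upper = yhat + tcrit * se_pred
  )
}

#' Regression diagnostics: leverage, Cook's distance, residual structure
#'
#' Computes the standard OLS influence diagnostics used to assess the model
#' assumptions: residual-vs-fitted pairs, ordered residual quantiles against
#' normal quantiles (Q-Q data, not an image), leverage from the projection
#' (hat) matrix diagonal, and Cook's distance.
#'
#' @param fit an [fit_its()] result.
#' @return list with tibbles `residuals_vs_fitted` (`fitted`, `residual`),
#'   `qq` (`theoretical`, `sample`), and `influence` (`t` row order,
#'   `leverage`, `cooks_distance`).
#' @export
compute_diagnostics <- function(fit) {
  h <- unname(stats::hatvalues(fit$lm))
  cd <- unname(stats::cooks.distance(fit$lm))
  r <- fit$residuals
  ord <- order(r)
  n <- length(r)
  list(
    residuals_vs_fitted = tibble::tibble(fitted = fit$fitted, residual = r),
    qq = tibble::tibble(
      theoretical = stats::qnorm(stats::ppoints(n)),
      sample = (r[ord] - mean(r)) / stats::sd(r)
    ),
    influence = tibble::tibble(
      row = seq_len(n),
      t = if (!is.null(fit$t)) fit$t else seq_len(n),
      leverage = h,
      cooks_distance = cd
    )
  )
}

#' Coefficient table in report layout
#'
#' @param fit an [fit_its()] result.
#' @param digits rounding applied for display; `NULL` keeps full precision.
#' @return tibble with `term`, `estimate`, `std.error`, `p.value`.
#' @export
coefficient_table <- function(fit, digits = 4) {
  out <- fit$coefficients[, c("term", "estimate", "std.error", "p.value")]
  if (!is.null(digits)) {
    out$estimate <- round(out$estimate, digits)
    out$std.error <- round(out$std.error, digits)
    out$p.value <- round(out$p.value, digits)
  }
  out
}
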