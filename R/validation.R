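#' Paired method-comparison container
#'
#' Holds paired measurements of the same specimens by two methods: the
#' `observed` values (the image pipeline) and the `standard` values (the
#' reference method, e.g. digital calipers). All comparison metrics
#' ([rmse()], [mae()], [rse()], [percent_metrics()], [linear_fit()])
#' operate on this container.
#'
#' @param observed Numeric vector of algorithm-derived values.
#' @param standard Numeric vector of reference values, same length.
#' @param df Residual degrees of freedom used by [rse()]; defaults to
#'   `n - 2`, the residual degrees of freedom of a two-parameter linear
#'   fit (clamped to a minimum of 1 so that two-point comparisons remain
#'   valid).
#' @return A `method_comparison` object with fields `observed`, `standard`,
#'   `n`, `df`.
#' @export
method_comparison <- function(observed, standard, df = NULL) {
  observed <- as.numeric(observed); standard <- as.numeric(standard)
  if (length(observed) != length(standard))
    stop("observed and standard must have equal length", call. = FALSE)
  n <- length(observed)
  if (n < 2L) stop("need at least 2 paired observations", call. = FALSE)
  if (anyNA(observed) || anyNA(standard))
    stop("paired observations must not contain NA", call. = FALSE)
  if (is.null(df)) df <- max(n - 2L, 1L)   # clamp so n = 2 pairs remain usable
  df <- as.numeric(df)
  if (is.na(df) || df < 1) stop("df must be >= 1", call. = FALSE)
  structure(list(observed = observed, standard = standard, n = n, df = df),
            class = "method_comparison")
}

as_comparison <- function(cmp) {
  if (!inherits(cmp, "method_comparison"))
    stop("expected a method_comparison; build one with method_comparison()",
         call. = FALSE)
  cmp
}

#' Root mean square error
#'
#' `sqrt(mean((observed - standard)^2))`.
#'
#' @param cmp A [method_comparison()].
#' @return RMSE in the trait's units.
#' @export
rmse <- function(cmp) {
  cmp <- as_comparison(cmp)
  sqrt(mean((cmp$observed - cmp$standard)^2))
}

#' Mean absolute error
#'
#' `mean(abs(observed - standard))`.
#'
#' @param cmp A [method_comparison()].
#' @return MAE in the trait's units.
#' @export
mae <- function(cmp) {
  cmp <- as_comparison(cmp)
  mean(abs(cmp$observed - cmp$standard))
}

#' Residual standard error
#'
#' `sqrt(sum((observed - standard)^2) / df)` — the regression-flavoured
#' sibling of RMSE, normalising the residual sum of squares by residual
#' degrees of freedom (`n - 2` by default) instead of `n`. The identity
#' `rse = rmse * sqrt(n / df)` always holds.
#'
#' @param cmp A [method_comparison()]; `cmp$df` sets the degrees of
#'   freedom.
#' @return RSE in the trait's units.
#' @export
rse <- function(cmp) {
  cmp <- as_comparison(cmp)
  sqrt(sum((cmp$observed - cmp$standard)^2) / cmp$df)
}

#' Percent-normalised error metrics
#'
#' Each absolute metric divided by the mean of the standard values, times
#' 100 — the scale-free form in which comparison errors are customarily
#' reported (error percentages depend on the trait's mean).
#'
#' @param cmp A [method_comparison()].
#' @return Named numeric `c(rmse_pct, mae_pct, rse_pct)`.
#' @export
percent_metrics <- function(cmp) {
  cmp <- as_comparison(cmp)
  m <- mean(cmp$standard)
  if (m == 0)
    stop("percent metrics undefined: mean of standard values is zero",
         call. = FALSE)
  c(rmse_pct = 100 * rmse(cmp) / m,
    mae_pct = 100 * mae(cmp) / m,
    rse_pct = 100 * rse(cmp) / m)
}

#' Ordinary least-squares fit of observed on standard
#'
#' The "fit of plot": `observed = intercept + slope * standard`, solved by
#' the closed-form normal equations; `r2` is the squared Pearson
#' correlation. Perfect method agreement gives slope 1, intercept 0,
#' r2 1.
#'
#' @param cmp A [method_comparison()] with `n >= 3` and non-constant
#'   standard values.
#' @return Named numeric `c(r2, slope, intercept)`.
#' @export
linear_fit <- function(cmp) {
  cmp <- as_comparison(cmp)
  if (cmp$n < 3L) stop("linear_fit needs at least 3 observations", call. = FALSE)
  s <- cmp$standard; o <- cmp$observed
  sxx <- sum((s - mean(s))^2)
  if (sxx == 0)
    stop("degenerate fit: standard values are constant", call. = FALSE)
  sxy <- sum((s - mean(s)) * (o - mean(o)))
  slope <- sxy / sxx
  intercept <- mean(o) - slope * mean(s)
  syy <- sum((o - mean(o))^2)
  r2 <- if (syy == 0) 1 else sxy^2 / (sxx * syy)
  c(r2 = r2, slope = slope, intercept = intercept)
}

#' Confidence and prediction bands of the method-comparison fit
#'
#' Standard OLS interval formulas around the [linear_fit()] line, for
#' plotting 95% confidence and prediction bands.
#'
#' @param cmp A [method_comparison()].
#' @param at Standard-axis values at which to evaluate the bands; defaults
#'   to a grid over the observed range.
#' @param level Coverage level (default 0.95).
#' @return A data frame with columns `standard`, `fit`, `conf_lo`,
#'   `conf_hi`, `pred_lo`, `pred_hi`.
#' @export
fit_bands <- function(cmp, at = NULL, level = 0.95) {
  cmp <- as_comparison(cmp)
  f <- linear_fit(cmp)
  s <- cmp$standard; o <- cmp$observed; n <- cmp$n
  if (is.null(at)) at <- seq(min(s), max(s), length.out = 100L)
  resid <- o - (f["intercept"] + f["slope"] * s)
  sigma2 <- sum(resid^2) / (n - 2)
  sxx <- sum((s - mean(s))^2)
  se_conf <- sqrt(sigma2 * (1 / n + (at - mean(s))^2 / sxx))
  se_pred <- sqrt(sigma2 * (1 + 1 / n + (at - mean(s))^2 / sxx))
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 2)
  fit <- f["intercept"] + f["slope"] * at
  data.frame(standard = at, fit = fit,
             conf_lo = fit - tq * se_conf, conf_hi = fit + tq * se_conf,
             pred_lo = fit - tq * se_pred, pred_hi = fit + tq * se_pred)
}

#' Full method-comparison report
#'
#' Computes every comparison metric at once: absolute RMSE/MAE/RSE, their
#' percent-normalised forms, and the linear-fit summary.
#'
#' @param observed,standard Paired numeric vectors (or pass a
#'   [method_comparison()] as `observed`).
#' @param df Residual degrees of freedom for [rse()] (default `n - 2`).
#' @return A `comparison_report`: a list with fields `rmse`, `mae`, `rse`,
#'   `rmse_pct`, `mae_pct`, `rse_pct`, `r2`, `slope`, `intercept`, `n`,
#'   `df`.
#' @export
compare_methods <- function(observed, standard = NULL, df = NULL) {
  cmp <- if (inherits(observed, "method_comparison")) observed
         else method_comparison(observed, standard, df)
  pct <- percent_metrics(cmp)
  fit <- linear_fit(cmp)
  structure(
    list(rmse = rmse(cmp), mae = mae(cmp), rse = rse(cmp),
         rmse_pct = unname(pct["rmse_pct"]), mae_pct = unname(pct["mae_pct"]),
         rse_pct = unname(pct["rse_pct"]),
         r2 = unname(fit["r2"]), slope = unname(fit["slope"]),
         intercept = unname(fit["intercept"]),
         n = cmp$n, df = cmp$df),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> n = %d, df = %g\n", x$n, x$df))
  cat(sprintf("  RMSE %.4f (%.3f%%)   MAE %.4f (%.3f%%)   RSE %.4f (%.3f%%)\n",
              x$rmse, x$rmse_pct, x$mae, x$mae_pct, x$rse, x$rse_pct))
  cat(sprintf("  fit: r2 = %.4f, slope = %.4f, intercept = %.4f\n",
              x$r2, x$slope, x$intercept))
  invisible(x)
}
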