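#' Per-year preseason climate aggregate
#'
#' Mean of a daily climate variable over the `window` days preceding a
#' fixed anchor date — the long-term mean growing-season start or end date
#' of the pixel/site (the same window every year, which avoids
#' selection-induced correlation with year-specific phenology). When the
#' anchor date is on or before the window length, the window borrows days
#' from the end of the previous calendar year; the first year is then
#' flagged missing.
#'
#' @param climate data.frame with columns `year`, `doy` and the variable.
#' @param var Name of the climate column (e.g. `"temperature"`).
#' @param mean_date Anchor DOY (long-term mean indicator date).
#' @param window Window length in days (default 30): DOYs
#'   `[mean_date - window, mean_date - 1]`.
#' @return data.frame `year, value` (NA where the window is incomplete).
#' @export
preseason_aggregate <- function(climate, var, mean_date, window = 30L) {
  if (window < 1L)
    stop_invalid_parameters("preseason_aggregate: window must be >= 1")
  if (!all(c("year", "doy", var) %in% names(climate)))
    stop_format_error(sprintf(
      "preseason_aggregate: climate needs columns year, doy, %s", var))
  anchor <- ceiling(mean_date)
  rel <- (anchor - window):(anchor - 1L)
  years <- sort(unique(climate$year))
  key <- climate$year * 1000L + climate$doy
  vals <- vapply(years, function(yr) {
    doys <- ifelse(rel >= 1L, rel, rel + DAYS_PER_YEAR)
    yrs <- ifelse(rel >= 1L, yr, yr - 1L)
    idx <- match(yrs * 1000L + doys, key)
    if (anyNA(idx)) return(NA_real_)
    v <- climate[[var]][idx]
    if (any(!is.finite(v))) NA_real_ else mean(v)
  }, numeric(1))
  data.frame(year = years, value = vals)
}

#' Per-year summer (June-July-August) climate aggregate
#'
#' Mean over DOY 152-243 of the fixed 365-day calendar. For precipitation
#' the conventional summary is the mean *monthly* total
#' (`mode = "monthly_total"`: JJA total divided by 3) rather than the daily
#' mean.
#'
#' @param climate data.frame with columns `year`, `doy` and the variable.
#' @param var Name of the climate column.
#' @param mode `"mean"` (default) or `"monthly_total"`.
#' @return data.frame `year, value` (NA where JJA coverage is incomplete).
#' @export
summer_aggregate <- function(climate, var, mode = c("mean", "monthly_total")) {
  mode <- match.arg(mode)
  if (!all(c("year", "doy", var) %in% names(climate)))
    stop_format_error(sprintf(
      "summer_aggregate: climate needs columns year, doy, %s", var))
  years <- sort(unique(climate$year))
  key <- climate$year * 1000L + climate$doy
  vals <- vapply(years, function(yr) {
    idx <- match(yr * 1000L + JJA_DOYS, key)
    if (anyNA(idx)) return(NA_real_)
    v <- climate[[var]][idx]
    if (any(!is.finite(v))) return(NA_real_)
    if (mode == "mean") mean(v) else sum(v) / 3
  }, numeric(1))
  data.frame(year = years, value = vals)
}

#' Climatic sensitivity of an indicator: correlation and OLS slope
#'
#' Pearson correlation (two-sided p) and OLS slope of a per-year indicator
#' on a per-year climate aggregate. Indicators enter in raw calendar units
#' (a larger growing-season start means a later start); any
#' "earlier-with-warming" sign flip belongs to reporting, not to this
#' computation.
#'
#' @param indicator Per-year indicator values.
#' @param climate Per-year climate values, same length.
#' @param min_years Minimum joint-finite years (default 5).
#' @return List of class `sensitivity_result`: `r`, `slope` (indicator
#'   units per climate unit), `slope_se` (OLS standard error of the slope),
#'   `p_value`, `n`, `defined` (FALSE when the climate series has zero
#'   variance).
#' @export
sensitivity <- function(indicator, climate, min_years = 5L) {
  if (length(indicator) != length(climate))
    stop_invalid_parameters("sensitivity: series differ in length")
  ok <- is.finite(indicator) & is.finite(climate)
  if (sum(ok) < min_years)
    stop_insufficient_data(sprintf(
      "sensitivity: %d joint-finite years < minimum %d", sum(ok), min_years))
  x <- climate[ok]
  y <- indicator[ok]
  if (stats::sd(x) == 0)
    return(structure(list(r = NA_real_, slope = NA_real_,
                          slope_se = NA_real_, p_value = NA_real_,
                          n = sum(ok), defined = FALSE),
                     class = "sensitivity_result"))
  ct <- stats::cor.test(x, y)
  slope <- stats::cov(x, y) / stats::var(x)
  resid <- y - mean(y) - slope * (x - mean(x))
  slope_se <- sqrt(sum(resid^2) / (sum(ok) - 2) / sum((x - mean(x))^2))
  structure(list(r = unname(ct$estimate), slope = slope,
                 slope_se = slope_se, p_value = ct$p.value, n = sum(ok),
                 defined = TRUE),
            class = "sensitivity_result")
}

#' Partial correlation controlling for two other climate variables
#'
#' Residual-on-residual Pearson correlation: the indicator and the target
#' climate variable are each regressed (with intercept) on the two control
#' variables, and the residuals are correlated. The p-value uses the t
#' distribution with n - 4 degrees of freedom (two controls plus
#' intercept plus the correlation itself).
#'
#' @param indicator Per-year indicator values.
#' @param target_climate Per-year target climate variable.
#' @param controls data.frame or matrix with 2 columns of control
#'   variables, same number of rows.
#' @param min_years Minimum joint-finite years (default 6).
#' @return List: `r` (partial correlation), `p_value`, `n`, `defined`
#'   (FALSE when the control design is singular).
#' @export
partial_correlation <- function(indicator, target_climate, controls,
                                min_years = 6L) {
  cm <- as.matrix(controls)
  if (ncol(cm) != 2L)
    stop_invalid_parameters("partial_correlation: exactly 2 control series required")
  ok <- is.finite(indicator) & is.finite(target_climate) &
    apply(is.finite(cm), 1, all)
  if (sum(ok) < min_years)
    stop_insufficient_data(sprintf(
      "partial_correlation: %d joint-finite years < minimum %d",
      sum(ok), min_years))
  X <- cbind(1, cm[ok, , drop = FALSE])
  if (qr(X)$rank < ncol(X))
    return(list(r = NA_real_, p_value = NA_real_, n = sum(ok), defined = FALSE))
  y <- indicator[ok]
  x <- target_climate[ok]
  res_y <- stats::lm.fit(X, y)$residuals
  res_x <- stats::lm.fit(X, x)$residuals
  # a series lying exactly in the span of the controls has nothing left to
  # correlate: its partial correlation is 0 (not rounding noise)
  if (sum(res_y^2) <= 1e-12 * sum((y - mean(y))^2) ||
      sum(res_x^2) <= 1e-12 * sum((x - mean(x))^2))
    return(list(r = 0, p_value = 1, n = sum(ok), defined = TRUE))
  if (stats::sd(res_x) == 0 || stats::sd(res_y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = sum(ok), defined = FALSE))
  r <- stats::cor(res_x, res_y)
  df <- sum(ok) - 4L
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(tval), df), n = sum(ok),
       defined = TRUE)
}
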