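#' Ordinary least-squares trend of an annual series
#'
#' @param years Calendar years (>= 3 finite points).
#' @param values Annual values, same length.
#' @return List of class `trend_result`: `slope` (units yr-1), `intercept`,
#'   `p_value` (two-sided t-test on the slope), `n_years`.
#' @export
ols_trend <- function(years, values) {
  ok <- is.finite(years) & is.finite(values)
  if (sum(ok) < 3L)
    stop_insufficient_data("ols_trend: need at least 3 finite points")
  fit <- stats::lm(values[ok] ~ years[ok])
  # constant series fit perfectly; summary()'s reminder about that is expected
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 p_value = sm$coefficients[2, "Pr(>|t|)"],
                 n_years = sum(ok)),
            class = "trend_result")
}

#' Relative contributions of the three components to the annual-GPP trend
#'
#' Each component's share is its slope's magnitude over the total absolute
#' magnitude of the three slopes, in percent, signed positive only when the
#' component's trend has the same sign as the annual-GPP trend:
#' `c_x = 100 * sign(slope_x * slope_gpp) * |slope_x| / (|slope_start| +
#' |slope_max| + |slope_end|)`. The absolute shares sum to 100.
#'
#' @param slope_start,slope_max,slope_end Trends of the three decomposed
#'   components (g C m-2 yr-1 per year).
#' @param gpp_trend Trend of annual GPP (sign only is used).
#' @return List of class `contribution_result`: `c_start, c_max, c_end`
#'   (signed %), `mode = "trend"`, `defined` (FALSE when all three slopes
#'   are zero, in which case the shares are NA).
#' @examples
#' trend_contributions(1, 2, 1, gpp_trend = 5)    # 25, 50, 25
#' trend_contributions(-1, 3, 0, gpp_trend = 5)   # -25, 75, 0
#' @export
trend_contributions <- function(slope_start, slope_max, slope_end, gpp_trend) {
  s <- c(start = slope_start, max = slope_max, end = slope_end)
  total <- sum(abs(s))
  if (total == 0 || !is.finite(total))
    return(structure(list(c_start = NA_real_, c_max = NA_real_,
                          c_end = NA_real_, mode = "trend", defined = FALSE),
                     class = "contribution_result"))
  shares <- 100 * sign(s * sign(gpp_trend)) * abs(s) / total
  structure(list(c_start = unname(shares["start"]),
                 c_max = unname(shares["max"]),
                 c_end = unname(shares["end"]),
                 mode = "trend", defined = TRUE),
            class = "contribution_result")
}

#' Consistency-weighted contributions to inter-annual variability
#'
#' Credits each component positively in years where it has the same sign as
#' the total reconstructed annual-GPP anomaly, weighted by that year's
#' anomaly magnitude:
#' `c_x = 100 * sum_i comp_x_i * sign(G_i) / sum_i |G_i|`,
#' where `G_i` is the reference anomaly of year i. With the reconstructed
#' reference (`G_i = comp_start_i + comp_max_i + comp_end_i`, the SMIPP
#' estimate of the anomaly) the signed shares sum to exactly 100; with the
#' observed annual-GPP anomaly as reference the closure is approximate.
#'
#' @param components data.frame or matrix with columns
#'   `comp_start, comp_max, comp_end` (one row per year), e.g. from
#'   [decompose_anomalies()].
#' @param reference `"reconstructed"` (default) or `"observed"`.
#' @param observed Observed annual-GPP anomalies (required when
#'   `reference = "observed"`).
#' @return List of class `contribution_result` with `mode = "iav"`.
#' @export
iav_contributions <- function(components, reference = c("reconstructed", "observed"),
                              observed = NULL) {
  reference <- match.arg(reference)
  cm <- as.matrix(as.data.frame(components)[, c("comp_start", "comp_max", "comp_end")])
  if (nrow(cm) < 3L)
    stop_insufficient_data("iav_contributions: need at least 3 years")
  g <- if (reference == "reconstructed") rowSums(cm) else {
    if (is.null(observed))
      stop_invalid_parameters("iav_contributions: observed anomalies required")
    observed
  }
  denom <- sum(abs(g))
  if (denom == 0)
    return(structure(list(c_start = NA_real_, c_max = NA_real_,
                          c_end = NA_real_, mode = "iav", defined = FALSE),
                     class = "contribution_result"))
  shares <- 100 * colSums(cm * sign(g)) / denom
  structure(list(c_start = unname(shares["comp_start"]),
                 c_max = unname(shares["comp_max"]),
                 c_end = unname(shares["comp_end"]),
                 mode = "iav", defined = TRUE),
            class = "contribution_result")
}

#' Spatial correlation between two trend (or mean) maps
#'
#' Pearson correlation across grid cells, treating pixels as observations.
#'
#' @param map_a,map_b Numeric vectors or matrices of the same shape; only
#'   jointly finite pixels enter (at least 10 required).
#' @return List: `r`, `r2`, `p_value`, `n`.
#' @export
spatial_correlation <- function(map_a, map_b) {
  a <- as.numeric(map_a)
  b <- as.numeric(map_b)
  if (length(a) != length(b))
    stop_invalid_parameters("spatial_correlation: maps differ in size")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 10L)
    stop_insufficient_data("spatial_correlation: fewer than 10 joint-finite pixels")
  ct <- stats::cor.test(a[ok], b[ok])
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p_value = ct$p.value, n = sum(ok))
}
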