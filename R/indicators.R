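#' Growing-season threshold from the long-term mean peak
#'
#' The threshold separating the growing season from the dormant season is a
#' fixed fraction (default 10%) of the long-term mean of the yearly smoothed
#' peak GPP, computed once per pixel/site and shared across its years.
#'
#' @param gpp_max_by_year Yearly smoothed peak GPP values (g C m-2 d-1);
#'   NAs are dropped.
#' @param fraction Fraction of the long-term mean peak (default 0.10), in
#'   (0, 1).
#' @return Object of class `threshold_spec`: `fraction`, `reference` (the
#'   long-term mean peak) and `threshold = fraction * reference`.
#' @examples
#' compute_threshold(c(8, 10, 12))$threshold  # 1
#' @export
compute_threshold <- function(gpp_max_by_year, fraction = 0.10) {
  if (fraction <= 0 || fraction >= 1)
    stop_invalid_parameters("compute_threshold: fraction must be in (0, 1)")
  v <- gpp_max_by_year[is.finite(gpp_max_by_year)]
  if (length(v) == 0L)
    stop_insufficient_data("compute_threshold: no valid yearly GPP_max values")
  reference <- mean(v)
  structure(list(fraction = fraction, reference = reference,
                 threshold = fraction * reference),
            class = "threshold_spec")
}

#' Extract phenology and physiology indicators from one smoothed curve
#'
#' Growing-season start (end) is the first (last) DOY of the year on which
#' the smoothed curve, clamped at 0, is at or above the threshold — whole
#' days, no sub-daily interpolation. The peak `gpp_max` is the maximum of
#' the clamped curve within `peak_window` (ties broken by the earliest
#' DOY). Years whose curve never reaches the threshold, or whose peak falls
#' outside `[gs_start, gs_end]` (pathological fits), are flagged invalid
#' rather than raised.
#'
#' @param curve A `smoothed_curve` (from [evaluate_curve()] or
#'   [ssa_smooth()]), or a bare numeric vector of 365 daily values.
#' @param threshold A `threshold_spec` from [compute_threshold()], or a
#'   single positive number.
#' @param peak_window DOY range searched for the peak. Defaults to 15:350
#'   for polynomial curves, whose tails can diverge at the year edges, and
#'   to the full year otherwise.
#' @return One-row data.frame: `year, gs_start, gpp_max, doy_of_max,
#'   gs_end, valid`.
#' @export
extract_indicators <- function(curve, threshold, peak_window = NULL) {
  if (is.numeric(curve))
    curve <- structure(list(values = curve, doys = seq_along(curve),
                            method = "raw", year = NA_integer_),
                       class = "smoothed_curve")
  stopifnot(inherits(curve, "smoothed_curve"))
  if (length(curve$values) != DAYS_PER_YEAR)
    stop_invalid_parameters("extract_indicators: curve must cover 365 days")
  thr <- if (inherits(threshold, "threshold_spec")) threshold$threshold else threshold
  if (!is.finite(thr) || thr <= 0)
    stop_invalid_parameters("extract_indicators: threshold must be > 0")
  if (is.null(peak_window))
    peak_window <- if (identical(curve$method, "polynomial")) 15:350
                   else seq_len(DAYS_PER_YEAR)

  clamped <- pmax(curve$values, 0)
  doy_of_max <- peak_window[which.max(clamped[peak_window])]
  gpp_max <- clamped[doy_of_max]
  above <- which(clamped >= thr)

  if (length(above) == 0L || gpp_max < thr) {
    return(data.frame(year = curve$year, gs_start = NA_integer_,
                      gpp_max = gpp_max, doy_of_max = doy_of_max,
                      gs_end = NA_integer_, valid = FALSE))
  }
  gs_start <- above[1L]
  gs_end <- above[length(above)]
  valid <- gs_start <= doy_of_max && doy_of_max <= gs_end
  data.frame(year = curve$year, gs_start = as.integer(gs_start),
             gpp_max = gpp_max, doy_of_max = as.integer(doy_of_max),
             gs_end = as.integer(gs_end), valid = valid)
}

#' Annual GPP total from one year of daily or 8-day GPP
#'
#' Daily series are summed; 8-day composites are weighted by the days each
#' composite covers (8 for composites 1-45, 5 for composite 46), so a
#' constant series of 1 integrates to 365 under either cadence.
#'
#' @param values One year of GPP (g C m-2 d-1): length 365 (daily) or 46
#'   (8-day).
#' @param cadence `"daily"` or `"8day"`; inferred from the length when
#'   omitted.
#' @param max_missing_frac Maximum tolerated fraction of missing steps;
#'   missing steps are filled with the mean of the observed ones.
#' @return Annual GPP (g C m-2 yr-1), or NA if too many steps are missing.
#' @export
annual_gpp <- function(values, cadence = NULL, max_missing_frac = 0.2) {
  if (is.null(cadence))
    cadence <- if (length(values) == N_COMPOSITES) "8day" else "daily"
  cadence <- match.arg(cadence, c("daily", "8day"))
  expected <- if (cadence == "daily") DAYS_PER_YEAR else N_COMPOSITES
  if (length(values) != expected)
    stop_invalid_parameters(sprintf(
      "annual_gpp: expected %d values for %s cadence, got %d",
      expected, cadence, length(values)))
  miss <- !is.finite(values)
  if (mean(miss) > max_missing_frac) return(NA_real_)
  if (any(miss)) values[miss] <- mean(values[!miss])
  if (cadence == "daily") sum(values) else sum(values * composite_lengths())
}

#' Per-year indicator table for a multi-year series
#'
#' The full indicator pipeline for one pixel or site: smooth each year
#' (degree-6 polynomial for 8-day composites, SSA for daily series), take
#' the long-term mean of the yearly smoothed peaks to fix the 10% threshold,
#' then extract `gs_start`, `gpp_max`, `gs_end` per year. Annual GPP is
#' integrated from the *raw* series, not the smoothed curve.
#'
#' @param series data.frame with columns `year`, `gpp`, and either `doy`
#'   (daily cadence) or `composite` (8-day cadence).
#' @param cadence `"daily"` or `"8day"`; inferred from the columns when
#'   omitted.
#' @param fraction Threshold fraction (default 0.10).
#' @param embed_window,n_components SSA settings (daily cadence).
#' @param degree Polynomial degree (8-day cadence).
#' @param max_missing_frac Missing-data tolerance per year; unusable years
#'   are flagged invalid.
#' @return data.frame (one row per year): `year, gs_start, gpp_max,
#'   doy_of_max, gs_end, annual_gpp, valid`, with the `threshold_spec` used
#'   attached as attribute `"threshold"`.
#' @export
extract_phenology <- function(series, cadence = NULL, fraction = 0.10,
                              embed_window = 120L, n_components = 4L,
                              degree = 6L, max_missing_frac = 0.2) {
  if (is.null(cadence))
    cadence <- if ("composite" %in% names(series)) "8day" else "daily"
  cadence <- match.arg(cadence, c("daily", "8day"))
  time_col <- if (cadence == "daily") "doy" else "composite"
  if (!all(c("year", time_col, "gpp") %in% names(series)))
    stop_format_error(sprintf(
      "extract_phenology: series must have columns year, %s, gpp", time_col))

  years <- sort(unique(series$year))
  n_steps <- if (cadence == "daily") DAYS_PER_YEAR else N_COMPOSITES
  curves <- vector("list", length(years))
  annual <- rep(NA_real_, length(years))
  for (i in seq_along(years)) {
    d <- series[series$year == years[i], ]
    vals <- rep(NA_real_, n_steps)
    vals[d[[time_col]]] <- d$gpp
    curves[[i]] <- tryCatch({
      if (cadence == "daily")
        ssa_smooth(vals, embed_window = embed_window,
                   n_components = n_components,
                   max_missing_frac = max_missing_frac, year = years[i])
      else
        evaluate_curve(fit_seasonal_polynomial(
          vals, degree = degree, max_missing_frac = max_missing_frac,
          year = years[i]))
    }, smipp_insufficient_data = function(e) NULL)
    annual[i] <- annual_gpp(vals, cadence, max_missing_frac = max_missing_frac)
  }

  peak_of <- function(cv) {
    if (is.null(cv)) return(NA_real_)
    w <- if (identical(cv$method, "polynomial")) 15:350 else seq_len(DAYS_PER_YEAR)
    max(pmax(cv$values[w], 0))
  }
  thr <- compute_threshold(vapply(curves, peak_of, numeric(1)), fraction)

  rows <- lapply(seq_along(years), function(i) {
    if (is.null(curves[[i]]))
      return(data.frame(year = years[i], gs_start = NA_integer_,
                        gpp_max = NA_real_, doy_of_max = NA_integer_,
                        gs_end = NA_integer_, valid = FALSE))
    rec <- extract_indicators(curves[[i]], thr)
    rec$year <- years[i]
    rec
  })
  out <- do.call(rbind, rows)
  out$annual_gpp <- annual
  out$valid <- out$valid & is.finite(annual)
  attr(out, "threshold") <- thr
  out
}
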