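#' Fit a sixth-degree seasonal polynomial to one year of 8-day GPP
#'
#' Ordinary least-squares fit of GPP on powers of DOY over the whole year,
#' the standard smoother for 8-day composite products. The predictor is
#' centred and scaled to `[-1, 1]` (`x = (doy - 183) / 182`) before forming
#' powers: raw DOY^6 reaches ~2e15 and destroys the conditioning of the
#' normal equations. Coefficients are stored in the scaled basis with the
#' transform recorded.
#'
#' Missing composites (NA) are tolerated up to `max_missing_frac` by
#' omission from the design; beyond that the year is unusable.
#'
#' @param values GPP composites (g C m-2 d-1), NA = missing.
#' @param doys Regression abscissae, same length as `values`, strictly
#'   increasing; defaults to the 46 composite mid-points
#'   ([composite_midpoint_doys()]).
#' @param degree Polynomial degree (default 6).
#' @param max_missing_frac Maximum tolerated fraction of missing composites
#'   (default 0.2).
#' @param year Optional year label carried through to the curve.
#' @return Object of class `seasonal_poly`: coefficients `a0..a<degree>` in
#'   the scaled basis, plus `center`, `scale`, `degree`, `year`.
#' @export
fit_seasonal_polynomial <- function(values, doys = composite_midpoint_doys(),
                                    degree = 6L, max_missing_frac = 0.2,
                                    year = NA_integer_) {
  if (length(values) != length(doys))
    stop_invalid_parameters("fit_seasonal_polynomial: values and doys differ in length")
  if (any(diff(doys) <= 0))
    stop_invalid_parameters("fit_seasonal_polynomial: doys must be strictly increasing")
  ok <- is.finite(values)
  if (mean(!ok) > max_missing_frac)
    stop_insufficient_data(sprintf(
      "fit_seasonal_polynomial: %.0f%% missing exceeds %.0f%% tolerance",
      100 * mean(!ok), 100 * max_missing_frac))
  if (sum(ok) < degree + 1L)
    stop_insufficient_data("fit_seasonal_polynomial: fewer points than coefficients")
  center <- 183
  scl <- 182
  x <- (doys[ok] - center) / scl
  X <- outer(x, 0:degree, `^`)
  fit <- stats::lm.fit(X, values[ok])
  if (fit$rank < degree + 1L)
    stop_insufficient_data("fit_seasonal_polynomial: rank-deficient design")
  structure(list(coefficients = stats::setNames(fit$coefficients,
                                                paste0("a", 0:degree)),
                 center = center, scale = scl, degree = as.integer(degree),
                 year = year),
            class = "seasonal_poly")
}

#' Evaluate a fitted seasonal polynomial as a daily curve
#'
#' @param curve A `seasonal_poly` from [fit_seasonal_polynomial()].
#' @param doys DOYs to evaluate at (default 1:365).
#' @return Object of class `smoothed_curve`: list with `values` (daily GPP,
#'   may be negative — clamping to 0 happens at indicator extraction),
#'   `doys`, `method = "polynomial"`, `year`.
#' @export
evaluate_curve <- function(curve, doys = seq_len(DAYS_PER_YEAR)) {
  stopifnot(inherits(curve, "seasonal_poly"))
  x <- (doys - curve$center) / curve$scale
  a <- curve$coefficients
  v <- rep(a[[curve$degree + 1L]], length(x))  # Horner in the scaled basis
  for (j in curve$degree:1) v <- v * x + a[[j]]
  structure(list(values = as.numeric(v), doys = doys, method = "polynomial",
                 year = curve$year),
            class = "smoothed_curve")
}

#' Singular spectrum analysis smoothing of one year of daily GPP
#'
#' Classical SSA: embed the series in an L x (N - L + 1) trajectory (Hankel)
#' matrix, take the singular value decomposition, and reconstruct from the
#' leading `n_components` eigentriples by anti-diagonal averaging. The
#' reconstruction is unique even though singular-vector signs are not.
#' `n_components` counts eigentriples (the default 4 keeps the lowest
#' frequency sub-signals, i.e. the seasonal shape, and discards the noise).
#'
#' Internal NA gaps up to `max_missing_frac` are linearly interpolated
#' before embedding (leading/trailing gaps take the nearest value).
#'
#' @param values One year of daily GPP (g C m-2 d-1); NA = missing.
#' @param embed_window Embedding window L in days (default 120: at least a
#'   season, at most about a third of the year).
#' @param n_components Number of leading eigentriples to keep (default 4).
#' @param max_missing_frac Maximum tolerated fraction of missing days
#'   (default 0.2).
#' @param year Optional year label.
#' @return Object of class `smoothed_curve` with `method = "ssa"`.
#' @export
ssa_smooth <- function(values, embed_window = 120L, n_components = 4L,
                       max_missing_frac = 0.2, year = NA_integer_) {
  n <- length(values)
  L <- as.integer(embed_window)
  k <- as.integer(n_components)
  if (L < 2L || L > n)
    stop_invalid_parameters("ssa_smooth: need 2 <= embed_window <= length(values)")
  if (k < 1L || k > L)
    stop_invalid_parameters("ssa_smooth: need 1 <= n_components <= embed_window")
  miss <- !is.finite(values)
  if (all(miss))
    stop_insufficient_data("ssa_smooth: all values missing")
  if (mean(miss) > max_missing_frac)
    stop_insufficient_data(sprintf(
      "ssa_smooth: %.0f%% missing exceeds %.0f%% tolerance",
      100 * mean(miss), 100 * max_missing_frac))
  if (any(miss))
    values <- stats::approx(which(!miss), values[!miss], xout = seq_len(n),
                            rule = 2)$y
  K <- n - L + 1L
  traj <- matrix(0, L, K)
  for (j in seq_len(K)) traj[, j] <- values[j:(j + L - 1L)]
  dec <- svd(traj, nu = k, nv = k)
  low_rank <- dec$u %*% (dec$d[seq_len(k)] * t(dec$v))
  rec <- numeric(n)
  cnt <- numeric(n)
  for (j in seq_len(K)) {
    idx <- j:(j + L - 1L)
    rec[idx] <- rec[idx] + low_rank[, j]
    cnt[idx] <- cnt[idx] + 1
  }
  structure(list(values = rec / cnt, doys = seq_len(n), method = "ssa",
                 year = year),
            class = "smoothed_curve")
}
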