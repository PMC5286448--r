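#' Smooth unimodal seasonal GPP curve with exact threshold crossings
#'
#' Builds one year's noise-free daily GPP curve as a symmetric sine-power
#' bump. The curve is zero outside a support slightly wider than
#' `[gs_start, gs_end]`, attains its maximum `gpp_max` at the season
#' mid-point, and crosses 10% of `gpp_max` exactly at `gs_start` (rising)
#' and `gs_end` (falling). The 10% crossing days are placed analytically, so
#' the generator's ground truth is exact rather than itself estimated.
#'
#' With mid-point m = (gs_start + gs_end)/2 and half-season h =
#' (gs_end - gs_start)/2, the curve is
#' `gpp_max * cos(pi (d - m) / (2 H))^shape` for `|d - m| < H` and 0
#' elsewhere, where `H = pi h / (2 acos(0.1^(1/shape)))` solves the 10%
#' crossing condition.
#'
#' @param gs_start,gs_end Growing-season start and end (DOY, may be
#'   fractional). Must satisfy `gs_start < gs_end`.
#' @param gpp_max Peak daily GPP (g C m-2 d-1), >= 0. Zero yields an
#'   all-zero curve.
#' @param shape Positive exponent of the sine-power bump (default 2).
#' @param doys DOYs at which to evaluate (default 1:365).
#' @return Numeric vector of daily GPP (g C m-2 d-1), same length as `doys`.
#' @examples
#' curve <- seasonal_curve(120, 280, 10)
#' max(curve)     # 10
#' curve[120]     # 1 = 10% of the maximum
#' @export
seasonal_curve <- function(gs_start, gs_end, gpp_max, shape = 2,
                           doys = seq_len(DAYS_PER_YEAR)) {
  if (!is.finite(gs_start) || !is.finite(gs_end) || gs_start >= gs_end)
    stop_invalid_parameters("seasonal_curve: gs_start must be < gs_end")
  if (!is.finite(gpp_max) || gpp_max < 0)
    stop_invalid_parameters("seasonal_curve: gpp_max must be >= 0")
  if (shape <= 0)
    stop_invalid_parameters("seasonal_curve: shape must be > 0")
  mid <- (gs_start + gs_end) / 2
  h <- (gs_end - gs_start) / 2
  half_support <- pi * h / (2 * acos(0.1^(1 / shape)))
  v <- numeric(length(doys))
  inside <- abs(doys - mid) < half_support
  v[inside] <- gpp_max * cos(pi * (doys[inside] - mid) / (2 * half_support))^shape
  v
}
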