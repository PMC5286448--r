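#' @keywords internal
"_PACKAGE"

# Fixed 365-day calendar: leap day dropped everywhere (8-day composite world).
DAYS_PER_YEAR <- 365L
N_COMPOSITES <- 46L

# DOY range of June-July-August on the 365-day calendar.
JJA_DOYS <- 152L:243L

#' First day of year of each 8-day composite
#'
#' Composite k covers DOY 8(k-1)+1 .. 8k for k = 1..45; composite 46 covers
#' the final 5 days (DOY 361-365).
#'
#' @return Integer vector of length 46.
#' @export
composite_start_doys <- function() {
  8L * (0:45) + 1L
}

#' Regression abscissa (mid-point DOY) of each 8-day composite
#'
#' Each composite is assigned the DOY of its first day + 3.5.
#'
#' @return Numeric vector of length 46.
#' @export
composite_midpoint_doys <- function() {
  composite_start_doys() + 3.5
}

# Days covered by each composite (8 for k = 1..45, 5 for k = 46).
composite_lengths <- function() {
  c(rep(8L, 45L), 5L)
}

#' Aggregate a daily series to 46 8-day composites
#'
#' @param values Numeric vector of length 365 (one year of daily values).
#' @return Numeric vector of length 46: the mean of the days in each
#'   composite (composite 46 averages 5 days).
#' @export
aggregate_8day <- function(values) {
  stopifnot(length(values) == DAYS_PER_YEAR)
  starts <- composite_start_doys()
  lens <- composite_lengths()
  vapply(seq_len(N_COMPOSITES),
         function(k) mean(values[starts[k]:(starts[k] + lens[k] - 1L)]),
         numeric(1))
}

# Map (year, doy on the 365-day calendar) to a real calendar Date, skipping
# Feb 29 in leap years.
doy_to_date <- function(year, doy) {
  is_leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  offset <- ifelse(is_leap & doy >= 60, doy, doy - 1)
  as.Date(paste0(year, "-01-01")) + offset
}

# Inverse of doy_to_date: Date -> list(year, doy) on the 365-day calendar;
# Feb 29 maps to NA doy (callers drop it).
date_to_doy <- function(date) {
  lt <- as.POSIXlt(date)
  year <- lt$year + 1900L
  yday <- lt$yday + 1L
  is_leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  doy <- ifelse(is_leap & yday == 60, NA_integer_,
                ifelse(is_leap & yday > 60, yday - 1L, yday))
  list(year = year, doy = as.integer(doy))
}

stop_insufficient_data <- function(msg) {
  stop(errorCondition(msg, class = c("smipp_insufficient_data", "smipp_error")))
}

stop_invalid_parameters <- function(msg) {
  stop(errorCondition(msg, class = c("smipp_invalid_parameters", "smipp_error")))
}

stop_format_error <- function(msg) {
  stop(errorCondition(msg, class = c("smipp_format_error", "smipp_error")))
}
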